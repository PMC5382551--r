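# Promoter scanning for the palindromic CRE element and intersection with
# a down-regulated gene set.

CRE_MOTIF <- "TGACGTCA"

#' Find exact occurrences of the CRE motif in a promoter
#'
#' Exact string matching on the given strand only, overlapping occurrences
#' included; `N` never matches. The default motif TGACGTCA is its own
#' reverse complement, so a single-strand scan is strand-complete; this is
#' verified at call time and recorded in the `strand_complete` attribute
#' (a message is emitted for non-palindromic motifs).
#'
#' @param promoter promoter sequence over `ACGTN`.
#' @param motif motif to scan for (default the palindromic CRE octamer);
#'   length >= 4.
#' @param gene gene id recorded on the hits.
#' @return data frame of hits: `gene`, `start`, `end` (0-based half-open),
#'   `matched`; attribute `strand_complete`.
#' @examples
#' find_cre_sites("TGACGTCATGACGTCA")  # two adjacent hits
#' @export
find_cre_sites <- function(promoter, motif = CRE_MOTIF,
                           gene = NA_character_) {
  p <- normalize_dna(promoter, allow_n = TRUE, what = "promoter sequence")
  m <- normalize_dna(motif, allow_n = FALSE, what = "motif")
  if (nchar(m) < 4L) {
    stop_mircons("mircons_parameter_error", "motif must be >= 4 nt")
  }
  palindromic <- identical(reverse_complement(m), m)
  if (!palindromic) {
    message("motif ", m, " is not its own reverse complement; ",
            "single-strand scan is not strand-complete")
  }
  starts <- match_starts(p, m)
  hits <- data.frame(gene = rep(gene, length(starts)), start = starts,
                     end = starts + nchar(m),
                     matched = rep(m, length(starts)),
                     stringsAsFactors = FALSE)
  attr(hits, "strand_complete") <- palindromic
  hits
}

#' Scan many promoters for a motif
#'
#' @param promoters named character vector of promoter sequences.
#' @inheritParams find_cre_sites
#' @return one data frame of hits across all promoters.
#' @export
scan_promoters <- function(promoters, motif = CRE_MOTIF) {
  stopifnot(!is.null(names(promoters)))
  out <- do.call(rbind, lapply(names(promoters), function(g) {
    suppressMessages(find_cre_sites(promoters[[g]], motif = motif,
                                    gene = g))
  }))
  if (is.null(out)) out <- find_cre_sites("", motif = motif)[0, ]
  attr(out, "strand_complete") <-
    identical(reverse_complement(normalize_dna(motif, FALSE)), toupper(motif))
  out
}

#' Intersect CRE hits with a down-regulated gene set
#'
#' Candidate transcription-factor targets are the genes of the
#' down-regulated set carrying at least one motif hit. Gene ids are
#' harmonized case-insensitively. The table reports every down-regulated
#' gene with its hit count, sorted by `n_cre` descending then gene id.
#'
#' @param hits data frame of motif hits (from [scan_promoters()]).
#' @param downregulated character vector of down-regulated gene ids.
#' @return data frame: `gene`, `n_cre`, `in_downregulated_set` (always
#'   `TRUE` in the table rows), `is_candidate` (`n_cre >= 1`),
#'   `first_hit_offset` (`NA` when no hit).
#' @export
intersect_with_gene_set <- function(hits, downregulated) {
  if (length(downregulated) == 0L) {
    warning("empty down-regulated gene set; no candidates")
    return(data.frame(gene = character(0), n_cre = integer(0),
                      in_downregulated_set = logical(0),
                      is_candidate = logical(0),
                      first_hit_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  down <- unique(downregulated)
  key <- toupper(down)
  hit_key <- toupper(hits$gene)
  n_cre <- vapply(key, function(k) sum(hit_key == k), 0L)
  first <- vapply(key, function(k) {
    s <- hits$start[hit_key == k]
    if (length(s)) min(s) else NA_integer_
  }, 0L)
  tab <- data.frame(gene = down, n_cre = as.integer(n_cre),
                    in_downregulated_set = TRUE,
                    is_candidate = n_cre >= 1L,
                    first_hit_offset = as.integer(first),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_cre, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
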