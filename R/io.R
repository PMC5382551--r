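# Format readers/writers: FASTA (via Biostrings), TSV with schema
# validation, BED6 for binding sites / motif hits.
# All intervals are 0-based half-open, BED-native.

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Duplicate ids, empty sequences and characters outside the nucleotide
#' alphabet (`ACGTUN`, either case) are rejected.
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences (`U`
#'   preserved).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_mircons("mircons_parse_error", "duplicate FASTA id(s): ",
                 paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(gsub("\r", "", as.character(set), fixed = TRUE))
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty)) {
    stop_mircons("mircons_parse_error", "empty sequence for record: ",
                 paste(empty, collapse = ", "))
  }
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop_mircons("mircons_parse_error", "illegal character in record: ",
                 paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param records named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  stopifnot(!is.null(names(records)))
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a tab-separated table with schema validation
#'
#' @param path TSV with a header row; `NA` marks missing values.
#' @param schema named character vector column -> type (`"character"`,
#'   `"numeric"`, `"integer"`); extra file columns are kept as character.
#' @return a data frame with typed columns, row order preserved.
#' @export
read_table <- function(path, schema) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "NA")
  missing <- setdiff(names(schema), names(tab))
  if (length(missing)) {
    stop_mircons("mircons_parse_error", "missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    raw <- tab[[col]]
    conv <- suppressWarnings(
      if (type == "integer") as.integer(raw) else as.numeric(raw))
    bad <- which(is.na(conv) & !is.na(raw))
    if (length(bad)) {
      stop_mircons("mircons_parse_error", "column '", col, "', row ",
                   bad[1L], ": cannot convert '", raw[bad[1L]], "' to ",
                   type)
    }
    tab[[col]] <- conv
  }
  tab
}

#' Write a data frame as TSV (`NA` for missing)
#'
#' @param table data frame.
#' @param path output file.
#' @export
write_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write binding sites or motif hits as BED6
#'
#' `chrom` is the gene id, intervals stay 0-based half-open (BED-native),
#' `name` is `mirna|site_type|predictors` (or the motif for CRE hits),
#' `score` is the supporting-predictor count, strand `+`.
#'
#' @param sites data frame with `gene`, `start`, `end` plus either
#'   merged-site columns (`mirna`, `site_type`, `predictors`,
#'   `n_predictors`) or a `matched` column (motif hits).
#' @param path output file.
#' @export
write_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("matched" %in% names(sites)) {
    sites$matched
  } else {
    preds <- if ("predictors" %in% names(sites)) sites$predictors else
      sites$predictor
    paste(sites$mirna, sites$site_type, preds, sep = "|")
  }
  score <- if ("n_predictors" %in% names(sites)) sites$n_predictors else 1L
  bed <- data.frame(chrom = sites$gene, start = sites$start,
                    end = sites$end, name = name, score = score,
                    strand = "+", stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path file with one gene id per line; blank lines ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write an array simulation to intensity/design TSV files
#'
#' Long intensity layout: `probe_id`, `array_id`, `channel` (R/G), `fg`,
#' `bg`; design: `array_id`, `group`.
#'
#' @param sim an `array_sim`.
#' @param intensities_path,design_path output files.
#' @export
write_intensities <- function(sim, intensities_path, design_path) {
  arrays <- colnames(sim$fg_r)
  long <- function(fg, bg, channel) {
    data.frame(probe_id = rep(sim$probe_ids, times = length(arrays)),
               array_id = rep(arrays, each = length(sim$probe_ids)),
               channel = channel, fg = as.vector(fg), bg = as.vector(bg),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(long(sim$fg_r, sim$bg_r, "R"),
               long(sim$fg_g, sim$bg_g, "G"))
  write_table(tab, intensities_path)
  write_table(data.frame(array_id = arrays,
                         group = unname(sim$group_labels),
                         stringsAsFactors = FALSE), design_path)
  invisible(intensities_path)
}

#' Read intensity/design TSV files back into an `array_sim`-shaped list
#'
#' @param intensities_path,design_path files written by
#'   [write_intensities()].
#' @param control_probes character vector of control probe ids (default:
#'   ids starting with `ctrl_`).
#' @return a list usable by [run_array_de()] (no `truth` field).
#' @export
read_intensities <- function(intensities_path, design_path,
                             control_probes = NULL) {
  tab <- read_table(intensities_path,
                    c(probe_id = "character", array_id = "character",
                      channel = "character", fg = "numeric",
                      bg = "numeric"))
  des <- read_table(design_path,
                    c(array_id = "character", group = "character"))
  probes <- unique(tab$probe_id)
  arrays <- des$array_id
  mat <- function(channel, what) {
    sub <- tab[tab$channel == channel, , drop = FALSE]
    m <- matrix(NA_real_, length(probes), length(arrays),
                dimnames = list(probes, arrays))
    m[cbind(match(sub$probe_id, probes), match(sub$array_id, arrays))] <-
      sub[[what]]
    m
  }
  if (is.null(control_probes)) {
    control_probes <- probes[startsWith(probes, "ctrl_")]
  }
  list(fg_r = mat("R", "fg"), fg_g = mat("G", "fg"),
       bg_r = mat("R", "bg"), bg_g = mat("G", "bg"),
       probe_ids = probes, control_probe_ids = control_probes,
       group_labels = stats::setNames(des$group, des$array_id))
}

#' Write a Cp table to TSV (long layout)
#'
#' Columns: `sample_id`, `group`, `gene_id`, `cp`.
#'
#' @param cp a [cp_table()].
#' @param path output file.
#' @export
write_cp_table <- function(cp, path) {
  stopifnot(inherits(cp, "cp_table"))
  samples <- rownames(cp$cp); genes <- colnames(cp$cp)
  tab <- data.frame(sample_id = rep(samples, times = length(genes)),
                    group = rep(unname(cp$group_labels),
                                times = length(genes)),
                    gene_id = rep(genes, each = length(samples)),
                    cp = as.vector(cp$cp), stringsAsFactors = FALSE)
  write_table(tab, path)
  invisible(path)
}

#' Read a long-layout Cp TSV into a [cp_table()]
#'
#' @param path file written by [write_cp_table()].
#' @param reference_gene reference gene id.
#' @export
read_cp_table <- function(path, reference_gene) {
  tab <- read_table(path, c(sample_id = "character", group = "character",
                            gene_id = "character", cp = "numeric"))
  samples <- unique(tab$sample_id); genes <- unique(tab$gene_id)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(tab$sample_id, samples), match(tab$gene_id, genes))] <-
    tab$cp
  groups <- tab$group[match(samples, tab$sample_id)]
  cp_table(m, stats::setNames(groups, samples), reference_gene)
}
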