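# Independent oracles used across the suite. These deliberately avoid the
# production code paths: reverse complements come from Biostrings, motif
# and seed-site detection use vectorized substring comparison, BH uses the
# literal step-up definition, and the normexp conditional expectation is
# computed by numerical quadrature.

rc_oracle <- function(s) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("Uu", "Tt", s))))
}

# brute-force seed-site detector: every 6mer-core window is tested with
# plain substring equality against the site-type definitions, strongest
# type kept per core locus
naive_seed_sites <- function(mirna_id, mirna_seq, utr, gene = NA_character_) {
  m <- chartr("U", "T", toupper(mirna_seq))
  u <- toupper(utr)
  L <- nchar(u)
  rc6 <- rc_oracle(substr(m, 2, 7))
  rc78 <- rc_oracle(substr(m, 2, 8))
  out <- list()
  if (L >= 6) {
    for (j in 0:(L - 6)) {                       # 0-based core start
      if (substring(u, j + 1, j + 6) != rc6) next
      if (j >= 1 && j + 7 <= L &&
          substring(u, j, j + 7) == paste0(rc78, "A")) {
        out[[length(out) + 1]] <- c(j - 1, j + 7, "8mer")
      } else if (j >= 1 && substring(u, j, j + 6) == rc78) {
        out[[length(out) + 1]] <- c(j - 1, j + 6, "7mer-m8")
      } else if (j + 7 <= L &&
                 substring(u, j + 1, j + 7) == paste0(rc6, "A")) {
        out[[length(out) + 1]] <- c(j, j + 7, "7mer-A1")
      } else {
        out[[length(out) + 1]] <- c(j, j + 6, "6mer")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  res <- data.frame(gene = gene, mirna = mirna_id,
                    start = as.integer(sapply(out, `[`, 1)),
                    end = as.integer(sapply(out, `[`, 2)),
                    site_type = sapply(out, `[`, 3),
                    stringsAsFactors = FALSE)
  res[order(res$start), ]
}

# per-position substring recount of exact motif occurrences
naive_motif_count <- function(seq, motif) {
  s <- toupper(seq)
  L <- nchar(s); w <- nchar(motif)
  if (L < w) return(0L)
  starts <- 1:(L - w + 1)
  sum(substring(s, starts, starts + w - 1) == motif)
}

naive_motif_starts <- function(seq, motif) {
  s <- toupper(seq)
  L <- nchar(s); w <- nchar(motif)
  if (L < w) return(integer(0))
  starts <- 1:(L - w + 1)
  which(substring(s, starts, starts + w - 1) == motif) - 1L
}

# literal Benjamini-Hochberg step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# E[S | X = x] for X = N(mu, sigma) + Exp(mean alpha) by quadrature; the
# posterior of S is concentrated near x - mu, so integrate a finite
# window wide enough to hold all its mass
quad_normexp <- function(x, mu, sigma, alpha) {
  w <- function(s) exp(-s / alpha) * dnorm(x - s, mean = mu, sd = sigma)
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(x - mu + 15 * sigma, 15 * sigma)
  num <- integrate(function(s) s * w(s), lo, hi, rel.tol = 1e-10)$value
  den <- integrate(w, lo, hi, rel.tol = 1e-10)$value
  num / den
}

# exact Mann-Whitney p by enumerating group assignments, with U computed
# by pair counting (independent of rank sums)
mw_enum_oracle <- function(x, y, alternative = "two_sided") {
  pool <- c(x, y)
  n <- length(x); m <- length(y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  eps <- 1e-9
  switch(alternative,
         two_sided = mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - eps),
         less = mean(us <= u_obs + eps),
         greater = mean(us >= u_obs - eps))
}

# naive pairwise interval-union merge to a fixpoint (per gene+miRNA);
# intervals merge iff they overlap by >= 1 nt (touching does not merge)
naive_merge_counts <- function(sites) {
  keys <- unique(paste(sites$gene, sites$mirna, sep = "\r"))
  counts <- integer(0)
  for (k in keys) {
    s <- sites[paste(sites$gene, sites$mirna, sep = "\r") == k, ]
    ints <- unname(cbind(s$start, s$end))
    repeat {
      merged_any <- FALSE
      for (i in seq_len(nrow(ints) - 1)) {
        for (j in seq(i + 1, nrow(ints))) {
          if (ints[i, 1] < ints[j, 2] && ints[j, 1] < ints[i, 2]) {
            ints[i, ] <- c(min(ints[i, 1], ints[j, 1]),
                           max(ints[i, 2], ints[j, 2]))
            ints <- ints[-j, , drop = FALSE]
            merged_any <- TRUE
            break
          }
        }
        if (merged_any) break
      }
      if (!merged_any || nrow(ints) == 1) break
    }
    counts[k] <- nrow(ints)
  }
  counts
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
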