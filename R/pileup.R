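#' Quality-filter a text pileup into base counts
#'
#' Parses a samtools-style multi-sample text pileup (columns `chrom`, `pos`,
#' `ref`, then per sample `depth`, `bases`, `qualities`) and rebuilds base
#' counts keeping only bases whose Phred quality is at or above `threshold`.
#' Per-base qualities are used only here, for filtering; downstream
#' likelihoods use the type-specific error model instead of per-base
#' qualities.
#'
#' Supported pileup base symbols: `.`/`,` (reference match), `ACGTacgt`,
#' `N`/`n` (counted to depth consumed but to no allele), `*` (deletion
#' placeholder, consumes a quality), `^X` read starts and `$` read ends,
#' and `+N`/`-N` indel descriptors (skipped; indels are out of scope).
#'
#' @param pileup Path to a pileup file, or a character vector of pileup
#'   lines.
#' @param threshold Minimum Phred quality to keep a base (default 20;
#'   `0` keeps everything).
#' @param individuals Optional ids for the samples; defaults to
#'   `ind0001 ...` in column order.
#' @return A [base_counts] object with `q_threshold = threshold`.
#' @export
quality_filter <- function(pileup, threshold = 20, individuals = NULL) {
  lines <- if (length(pileup) == 1L && file.exists(pileup)) {
    readLines(pileup)
  } else {
    as.character(pileup)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty pileup input", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  n_samples <- (nf[1] - 3L) / 3L
  bad <- which(nf < 6L | (nf - 3L) %% 3L != 0L | nf != nf[1])
  if (length(bad) > 0) {
    stop("malformed pileup line ", bad[1], ": expected 3 + 3*k fields",
         call. = FALSE)
  }
  if (is.null(individuals)) {
    individuals <- sprintf("ind%04d", seq_len(n_samples))
  }
  stopifnot(length(individuals) == n_samples)

  ns <- length(lines)
  mats <- lapply(ALLELES, function(a) matrix(0L, ns, n_samples))
  names(mats) <- ALLELES
  chrom <- character(ns)
  pos <- integer(ns)
  for (li in seq_len(ns)) {
    f <- fields[[li]]
    chrom[li] <- f[1]
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p) || p < 1L) {
      stop("malformed pileup line ", li, ": bad position '", f[2], "'",
           call. = FALSE)
    }
    pos[li] <- p
    ref <- toupper(f[3])
    for (s in seq_len(n_samples)) {
      bases <- f[3L + 3L * (s - 1L) + 2L]
      quals <- f[3L + 3L * (s - 1L) + 3L]
      if (bases == "*" && quals == "*") next  # empty sample column
      parsed <- parse_pileup_bases(bases, ref, li)
      q <- utf8ToInt(quals) - 33L
      if (length(q) != length(parsed)) {
        stop("malformed pileup line ", li, ": ", length(parsed),
             " bases vs ", length(q), " quality characters", call. = FALSE)
      }
      keep <- parsed[q >= threshold]
      keep <- keep[keep %in% ALLELES]
      if (length(keep) > 0) {
        tab <- table(factor(keep, levels = ALLELES))
        for (a in ALLELES) mats[[a]][li, s] <- mats[[a]][li, s] + tab[[a]]
      }
    }
  }
  base_counts(mats, sites = tibble(chrom = chrom, pos = pos),
              individuals = individuals, q_threshold = threshold)
}

# Expand one pileup base string into a vector of upper-case base calls
# ("A","C","G","T","N","*"), one per quality character.
parse_pileup_bases <- function(bases, ref, line_no) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # caret + mapping-quality char, no base consumed
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- suppressWarnings(as.integer(paste(chars[(i + 1L):(j - 1L)],
                                               collapse = "")))
      if (is.na(len)) {
        stop("malformed pileup line ", line_no, ": bad indel descriptor",
             call. = FALSE)
      }
      i <- j + len  # skip inserted/deleted sequence
    } else if (ch %in% c(".", ",")) {
      out <- c(out, ref)
      i <- i + 1L
    } else if (toupper(ch) %in% c(ALLELES, "N") || ch == "*") {
      out <- c(out, toupper(ch))
      i <- i + 1L
    } else {
      stop("malformed pileup line ", line_no, ": unexpected character '",
           ch, "'", call. = FALSE)
    }
  }
  out
}
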