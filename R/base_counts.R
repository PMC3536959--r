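#' Per-site, per-individual base counts
#'
#' The stage-1 data unit: for every site and individual, the number of
#' quality-filtered sequenced bases observed as A, C, G and T. Counts are
#' stored as four sites-by-individuals integer matrices for fast vectorised
#' likelihood computation; [as_tibble()] converts to/from the long tabular
#' form used on disk.
#'
#' @param counts A data frame with columns `chrom`, `pos`, `indiv`, `nA`,
#'   `nC`, `nG`, `nT` (one row per site x individual; absent combinations
#'   are depth 0), or a named list of four sites-by-individuals matrices
#'   `A`, `C`, `G`, `T`.
#' @param sites When `counts` is a matrix list: a data frame with `chrom`
#'   and `pos` (1-based) for each row.
#' @param individuals When `counts` is a matrix list: individual ids for
#'   each column.
#' @param q_threshold Base-quality threshold the counts were filtered at
#'   (Phred scale; default 20, i.e. a 1% error rate by quality definition).
#' @return An object of class `base_counts`.
#' @export
base_counts <- function(counts, sites = NULL, individuals = NULL,
                        q_threshold = 20) {
  if (is.data.frame(counts)) {
    return(base_counts_from_tibble(counts, q_threshold = q_threshold))
  }
  stopifnot(
    is.list(counts), identical(names(counts), ALLELES),
    !is.null(sites), !is.null(individuals)
  )
  dims <- dim(counts[[1]])
  for (a in ALLELES) {
    m <- counts[[a]]
    stopifnot(is.matrix(m), identical(dim(m), dims))
    if (any(m < 0)) stop("negative base counts", call. = FALSE)
    storage.mode(counts[[a]]) <- "integer"
  }
  stopifnot(nrow(sites) == dims[1], length(individuals) == dims[2])
  sites <- as_tibble(sites[, c("chrom", "pos")])
  sites$chrom <- as.character(sites$chrom)  # stable type across TSV round-trips
  sites$pos <- as.integer(sites$pos)
  structure(
    list(
      counts = counts,
      sites = sites,
      individuals = as.character(individuals),
      q_threshold = q_threshold
    ),
    class = "base_counts"
  )
}

base_counts_from_tibble <- function(df, q_threshold = 20) {
  needed <- c("chrom", "pos", "indiv", "nA", "nC", "nG", "nT")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("base-count table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cnt <- as.matrix(df[, c("nA", "nC", "nG", "nT")])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    bad <- which(rowSums(is.na(cnt) | cnt < 0 | cnt != round(cnt)) > 0)
    stop("invalid base counts at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  site_key <- paste(df$chrom, df$pos, sep = ":")
  dup <- duplicated(paste(site_key, df$indiv, sep = "/"))
  if (any(dup)) {
    stop("duplicate (site, individual) rows at row(s): ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  sites <- dplyr::distinct(df[, c("chrom", "pos")])
  site_levels <- paste(sites$chrom, sites$pos, sep = ":")
  indivs <- unique(as.character(df$indiv))
  i <- match(site_key, site_levels)
  j <- match(as.character(df$indiv), indivs)
  mats <- lapply(c(nA = "nA", nC = "nC", nG = "nG", nT = "nT"), function(col) {
    m <- matrix(0L, nrow(sites), length(indivs))
    m[cbind(i, j)] <- as.integer(df[[col]])
    m
  })
  names(mats) <- ALLELES
  base_counts(mats, sites = sites, individuals = indivs,
              q_threshold = q_threshold)
}

#' @export
print.base_counts <- function(x, ...) {
  cat("<base_counts> ", nrow(x$sites), " sites x ", length(x$individuals),
      " individuals (Q>=", x$q_threshold, ")\n", sep = "")
  cat("  mean depth/site/individual: ",
      signif(mean(depth_matrix(x)), 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble base_counts
#' @rdname base_counts
#' @param x A `base_counts` object.
#' @param ... Unused.
as_tibble.base_counts <- function(x, ...) {
  ns <- nrow(x$sites)
  ni <- length(x$individuals)
  tibble(
    chrom = rep(x$sites$chrom, times = ni),
    pos = rep(x$sites$pos, times = ni),
    indiv = rep(x$individuals, each = ns),
    nA = as.vector(x$counts$A),
    nC = as.vector(x$counts$C),
    nG = as.vector(x$counts$G),
    nT = as.vector(x$counts$T)
  )
}

#' Depth helpers for base counts
#'
#' @param x A `base_counts` object.
#' @return `depth_matrix()` returns the sites-by-individuals matrix of total
#'   filtered depth; `total_depth()` the per-site depth summed across
#'   individuals.
#' @export
depth_matrix <- function(x) {
  stopifnot(inherits(x, "base_counts"))
  x$counts$A + x$counts$C + x$counts$G + x$counts$T
}

#' @rdname depth_matrix
#' @export
total_depth <- function(x) {
  rowSums(depth_matrix(x))
}

# Pooled (across individuals) count of each base per site: sites x 4 matrix.
pooled_counts <- function(x) {
  out <- vapply(ALLELES, function(a) rowSums(x$counts[[a]]),
                numeric(nrow(x$sites)))
  if (nrow(x$sites) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, ALLELES))
  out
}

# Most-supported allele per site, ties broken by A < C < G < T.
site_major_allele <- function(x) {
  pc <- pooled_counts(x)
  ALLELES[apply(pc, 1, which.max)]
}
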