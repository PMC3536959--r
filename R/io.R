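#' Read and write base-count tables
#'
#' The native on-disk form of a [base_counts] object: a tab-separated
#' file with header `chrom pos indiv nA nC nG nT`, positions 1-based,
#' one row per (site, individual). Duplicate (site, individual) rows,
#' negative or non-integer counts are rejected with the offending line
#' number. Absent combinations read back as depth 0.
#'
#' @param path File path.
#' @param q_threshold Quality threshold recorded on the object
#'   (default 20).
#' @return `read_basecount_tsv()` returns a [base_counts];
#'   `write_basecount_tsv()` returns `path` invisibly.
#' @export
read_basecount_tsv <- function(path, q_threshold = 20) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(chrom = "character"),
                          check.names = FALSE)
  needed <- c("chrom", "pos", "indiv", "nA", "nC", "nG", "nT")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("base-count file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(base_counts(
      list(A = matrix(0L, 0, 0), C = matrix(0L, 0, 0),
           G = matrix(0L, 0, 0), T = matrix(0L, 0, 0)),
      sites = tibble(chrom = character(), pos = integer()),
      individuals = character(), q_threshold = q_threshold
    ))
  }
  tryCatch(
    base_counts_from_tibble(df, q_threshold = q_threshold),
    error = function(e) {
      # translate data-frame row indices to file line numbers (+1 header)
      stop(gsub("row\\(s\\): ([0-9, ]+)", "row(s): \\1 (add 1 for the header line)",
                conditionMessage(e)), call. = FALSE)
    }
  )
}

#' @rdname read_basecount_tsv
#' @param x A [base_counts] object.
#' @export
write_basecount_tsv <- function(x, path) {
  stopifnot(inherits(x, "base_counts"))
  df <- as_tibble(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write result tables
#'
#' Results travel as tab-separated text with a stable column order equal
#' to the column order of the data frame written. Non-integer numeric
#' columns are serialised at 6 significant figures; p-value columns
#' (names equal to or starting with `p`, `p_`, or ending `_p`) use
#' scientific notation. Values round-trip at that precision.
#'
#' @param df A data frame of results.
#' @param path File path.
#' @param required_cols For `read_results()`: columns that must be
#'   present; a schema mismatch names the missing columns.
#' @return `read_results()` returns a tibble; `write_results()` returns
#'   `path` invisibly.
#' @export
write_results <- function(df, path) {
  out <- as.data.frame(df)
  is_p <- grepl("^p($|_)", names(out)) | grepl("_p$", names(out))
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.double(x)) {
      out[[j]] <- if (is_p[j]) {
        ifelse(is.na(x), NA, sprintf("%.5e", x))
      } else {
        ifelse(is.na(x), NA, sprintf("%.6g", signif(x, 6)))
      }
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, required_cols = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "NA")
  if (!is.null(required_cols)) {
    missing_cols <- setdiff(required_cols, names(df))
    if (length(missing_cols) > 0) {
      stop("result file ", path, " is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  as_tibble(df)
}

#' Write discovered sites as minimal VCF 4.2
#'
#' One record per site with `REF` = major allele, `ALT` = best minor
#' allele and `INFO AF=` the estimated minor-allele frequency. Positions
#' are written 1-based as stored (VCF is itself 1-based; no coordinate
#' shift applies).
#'
#' @param sites A site table with `chrom`, `pos`, `major`, `minor`,
#'   `f_hat` (e.g. from [discover_snps()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "major", "minor", "f_hat") %in%
                  names(sites)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=exomassoc",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Estimated minor allele frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(sites) > 0) {
    id <- if ("site" %in% names(sites)) sites$site else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tAF=%s",
                       sites$chrom, as.integer(sites$pos), id,
                       sites$major, sites$minor,
                       sprintf("%.6g", sites$f_hat)), con)
  }
  invisible(path)
}

#' Write cohort genotype and phenotype tables
#'
#' Genotypes go out as a site-by-individual TSV of minor-allele dosages
#' (`NA` for missing), with the site table columns first; phenotypes as
#' a plain per-individual TSV.
#'
#' @param cohort A `cohort`.
#' @param geno_path,pheno_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_cohort_tsv <- function(cohort, geno_path, pheno_path) {
  stopifnot(inherits(cohort, "cohort"))
  g <- cbind(cohort$sites[, c("site", "chrom", "pos", "major", "minor")],
             as.data.frame(cohort$genotypes))
  utils::write.table(g, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$phenotypes, pheno_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(geno_path, pheno_path))
}
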