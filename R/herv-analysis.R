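#' Parse a HERV locus name into family, cytoband and copy letter
#'
#' Locus names follow the `FAMILY_band[letter]` convention, e.g.
#' `MER101_6q27d` is copy `d` of family MER101 on cytoband 6q27, and
#' `HERVK11D_19p13.2a` is copy `a` on the dotted band 19p13.2. The family is
#' the substring before the final underscore; a trailing lowercase letter
#' after the band digits is the copy suffix.
#'
#' @param locus_id character vector of locus names.
#' @return data.frame with `family`, `cytoband`, `copy_suffix` (empty string
#'   when absent). Names without an underscore yield the whole string as the
#'   family, an empty cytoband, and a warning.
#' @export
parse_locus_name <- function(locus_id) {
  has_us <- grepl("_", locus_id, fixed = TRUE)
  if (any(!has_us))
    warning("locus name(s) without underscore: ",
            paste(utils::head(locus_id[!has_us], 5), collapse = ", "))
  family <- ifelse(has_us, sub("_[^_]*$", "", locus_id), locus_id)
  rest <- ifelse(has_us, sub("^.*_", "", locus_id), "")
  suffix <- sub("^.*?([a-z]?)$", "\\1", sub("^(.*[0-9])", "", rest))
  cytoband <- substr(rest, 1, nchar(rest) - nchar(suffix))
  data.frame(family = family, cytoband = cytoband, copy_suffix = suffix,
             stringsAsFactors = FALSE)
}

#' Family over-representation among differentially expressed HERV loci
#'
#' For every family in the annotation database, compares the family's
#' frequency among DE loci with its frequency in the database:
#' `ratio = freq_de / freq_db`. Under proportional sampling all ratios are
#' 1, so 1 is the expected ratio; the unnormalized count ratio
#' `total_db / total_de` is also reported (`attr(, "db_over_de")`) for
#' comparison with displays that use it as a reference line.
#'
#' @param de_loci character vector of DE locus ids (subset of the database).
#' @param db_loci locus annotation data.frame with a `family` column (falls
#'   back to [parse_locus_name()] when absent).
#' @param hypergeom if `TRUE`, attach a hypergeometric enrichment p-value per
#'   family with BH-adjusted q.
#' @return data.frame (`family`, `n_db`, `n_de`, `freq_db`, `freq_de`,
#'   `ratio`), sorted by ratio descending; `attr(, "expected_ratio") = 1`.
#' @export
family_enrichment <- function(de_loci, db_loci, hypergeom = FALSE) {
  fam <- db_loci$family
  if (is.null(fam)) fam <- parse_locus_name(db_loci$locus_id)$family
  unknown <- setdiff(de_loci, db_loci$locus_id)
  if (length(unknown))
    stop("DE locus id(s) not in database: ", paste(unknown, collapse = ", "))
  total_db <- nrow(db_loci)
  total_de <- length(de_loci)
  n_db <- table(fam)
  de_fam <- fam[match(de_loci, db_loci$locus_id)]
  n_de <- table(factor(de_fam, levels = names(n_db)))
  out <- data.frame(
    family = names(n_db),
    n_db = as.integer(n_db),
    n_de = as.integer(n_de),
    stringsAsFactors = FALSE
  )
  out$freq_db <- out$n_db / total_db
  out$freq_de <- if (total_de > 0) out$n_de / total_de else 0
  out$ratio <- ifelse(out$n_db > 0, out$freq_de / out$freq_db, NA_real_)
  if (hypergeom) {
    out$p <- stats::phyper(out$n_de - 1, out$n_db, total_db - out$n_db,
                           total_de, lower.tail = FALSE)
    out$q <- bh_adjust(out$p)
  }
  out <- out[order(-out$ratio, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "expected_ratio") <- 1
  attr(out, "db_over_de") <- if (total_de > 0) total_db / total_de else NA_real_
  out
}

#' Per-chromosome distribution of DE loci against the database
#'
#' Counts DE and database loci per chromosome; the table is a suitable input
#' for circular genome-overview plots.
#'
#' @param de_loci character vector of DE locus ids.
#' @param db locus annotation data.frame.
#' @return data.frame with `chrom`, `n_de`, `n_db`.
#' @export
chromosome_distribution <- function(de_loci, db) {
  unknown <- setdiff(de_loci, db$locus_id)
  if (length(unknown))
    stop("DE locus id(s) not in database: ", paste(unknown, collapse = ", "))
  n_db <- table(db$chrom)
  de_chrom <- db$chrom[match(de_loci, db$locus_id)]
  n_de <- table(factor(de_chrom, levels = names(n_db)))
  data.frame(chrom = names(n_db), n_de = as.integer(n_de),
             n_db = as.integer(n_db), stringsAsFactors = FALSE)
}
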