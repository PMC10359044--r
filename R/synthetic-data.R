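#' Generate a toy genome annotation of HERV loci and genes
#'
#' Lays out non-overlapping genes and HERV loci on a small set of toy
#' chromosomes (1 Mb each, at most 5). Locus family labels are drawn from
#' `family_weights`, emulating the strongly skewed family-frequency
#' distribution of real proviral annotation databases. A fraction
#' `frac_intragenic` of loci are placed inside gene bodies; the rest fall in
#' intergenic space so that each has a well-defined nearest upstream and
#' downstream gene. Locus names follow the `FAMILY_band` convention with a
#' lowercase copy letter appended when a family recurs on the same cytoband
#' (e.g. `MER101_6q27d`).
#'
#' @param n_loci,n_genes number of HERV loci and genes to place.
#' @param n_chromosomes number of toy chromosomes (1--5), each 1 Mb.
#' @param family_weights named numeric vector of relative family frequencies.
#' @param frac_intragenic fraction of loci placed inside a gene body.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with elements `loci` and `genes`: annotation data.frames with
#'   0-based half-open coordinates. Chromosome lengths are attached to `loci`
#'   as the `"chrom_lengths"` attribute.
#' @export
make_toy_annotation <- function(n_loci, n_genes, n_chromosomes = 3,
                                family_weights = c(HML2 = 4, MER101 = 2, HERVH = 2,
                                                   HERVW = 1, HERVK11D = 1),
                                frac_intragenic = 0.25, seed = 1) {
  stopifnot(n_loci >= 1, n_genes >= 0, length(family_weights) >= 1,
            frac_intragenic >= 0, frac_intragenic <= 1)
  if (n_chromosomes < 1 || n_chromosomes > 5)
    stop("n_chromosomes must be between 1 and 5")
  chrom_len <- 1e6L
  chroms <- paste0("chr", seq_len(n_chromosomes))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # Sequential layout per chromosome: alternate random-length genes and gaps.
  cursor <- stats::setNames(rep(0L, n_chromosomes), chroms)
  genes <- NULL
  if (n_genes > 0) {
    g_chrom <- chroms[rep_len(seq_len(n_chromosomes), n_genes)]
    g_len <- as.integer(round(stats::runif(n_genes, 2000, 8000)))
    g_gap <- as.integer(round(stats::runif(n_genes, 1500, 5000)))
    starts <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      ch <- g_chrom[i]
      starts[i] <- cursor[ch] + g_gap[i]
      cursor[ch] <- starts[i] + g_len[i]
      if (cursor[ch] > chrom_len)
        stop("capacity error: ", n_genes, " genes do not fit on ",
             n_chromosomes, " toy chromosome(s)")
    }
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = g_chrom,
      start = starts,
      end = starts + g_len,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = sample(c("protein_coding", "lncRNA"), n_genes,
                       replace = TRUE, prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE
    )
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), biotype = character(),
                        stringsAsFactors = FALSE)
  }

  n_intra <- as.integer(round(frac_intragenic * n_loci))
  if (n_intra > n_genes)
    stop("capacity error: frac_intragenic requires ", n_intra,
         " host genes but only ", n_genes, " are available")
  n_inter <- n_loci - n_intra

  loc_chrom <- character(n_loci)
  loc_start <- integer(n_loci)
  loc_end <- integer(n_loci)
  loc_len <- as.integer(round(stats::runif(n_loci, 300, 1200)))

  # Intragenic loci: one per host gene, sampled without replacement.
  if (n_intra > 0) {
    hosts <- sample.int(n_genes, n_intra)
    for (k in seq_len(n_intra)) {
      g <- hosts[k]
      len <- min(loc_len[k], genes$end[g] - genes$start[g])
      s <- genes$start[g] +
        as.integer(floor(stats::runif(1, 0, genes$end[g] - genes$start[g] - len + 1)))
      loc_chrom[k] <- genes$chrom[g]; loc_start[k] <- s; loc_end[k] <- s + len
    }
  }

  # Intergenic loci: carve free intervals out of the gene-free space and place
  # one locus per draw, splitting the interval so loci never overlap.
  if (n_inter > 0) {
    free <- list()
    for (ch in chroms) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      bounds <- c(0L, as.vector(rbind(g$start, g$end)), chrom_len)
      starts <- bounds[seq(1, length(bounds), by = 2)]
      ends <- bounds[seq(2, length(bounds), by = 2)]
      keep <- ends - starts > 2
      free <- c(free, Map(function(s, e) list(chrom = ch, start = s, end = e),
                          starts[keep], ends[keep]))
    }
    for (k in seq_len(n_inter)) {
      i <- n_intra + k
      len <- loc_len[i]
      ok <- which(vapply(free, function(f) f$end - f$start >= len + 2, logical(1)))
      if (!length(ok)) stop("capacity error: no intergenic space left for locus ", i)
      f <- free[[sample(ok, 1)]]
      s <- f$start + 1L +
        as.integer(floor(stats::runif(1, 0, f$end - f$start - len - 1)))
      loc_chrom[i] <- f$chrom; loc_start[i] <- s; loc_end[i] <- s + len
      free <- c(free[-match(list(f), free)],
                list(list(chrom = f$chrom, start = f$start, end = s),
                     list(chrom = f$chrom, start = s + len, end = f$end)))
      free <- Filter(function(g) g$end - g$start > 2, free)
    }
  }

  fams <- sample(names(family_weights), n_loci, replace = TRUE,
                 prob = family_weights / sum(family_weights))
  band <- paste0(sub("chr", "", loc_chrom),
                 ifelse(loc_start < 0.45 * chrom_len, "p", "q"),
                 1L + loc_start %/% 50000L)
  locus_id <- paste0(fams, "_", band)
  # copy letters disambiguate recurrences of a family on the same band
  dup_grp <- ave(seq_along(locus_id), locus_id, FUN = seq_along)
  n_grp <- ave(seq_along(locus_id), locus_id, FUN = length)
  locus_id <- ifelse(n_grp > 1, paste0(locus_id, letters[dup_grp]), locus_id)

  loci <- data.frame(
    locus_id = locus_id, chrom = loc_chrom, start = loc_start, end = loc_end,
    strand = sample(c("+", "-"), n_loci, replace = TRUE),
    family = fams, stringsAsFactors = FALSE
  )
  ord <- order(loci$chrom, loci$start)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  attr(loci, "chrom_lengths") <- stats::setNames(rep(chrom_len, n_chromosomes), chroms)
  list(loci = loci, genes = genes)
}

# Save/restore global RNG state so generators are pure in their seed without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate multi-mapped fragments over HERV loci and write them as SAM
#'
#' Each fragment originates from one true locus drawn from
#' `true_proportions`. With probability `ambiguity_rate` it additionally
#' aligns to 1--3 decoy loci whose alignment score is lower than the true
#' alignment by a Poisson(`score_gap`) deficit (`score_gap = 0` gives exact
#' score ties). Alignment scores are emitted in the `AS:i` tag, higher is
#' better; decoy records carry the secondary-alignment flag. The true locus
#' of every fragment is recorded in the returned truth table.
#'
#' @param loci locus annotation data.frame from [make_toy_annotation()].
#' @param true_proportions named simplex vector over exactly the given locus
#'   ids.
#' @param n_fragments number of fragments.
#' @param ambiguity_rate fraction of fragments receiving decoy alignments.
#' @param score_gap mean score deficit of decoy alignments (Poisson rate).
#' @param seed integer seed; output is byte-identical for identical arguments.
#' @param sam_path output SAM path.
#' @param read_length read length in bp (clipped to the locus).
#' @param base_score alignment score of the true alignment.
#' @return List with `sam` (the path), `truth` (data.frame `fragment_id`,
#'   `true_locus`, `ambiguous`) and `sim_truth` (list recording
#'   `true_proportions` and `seed`).
#' @export
simulate_fragments <- function(loci, true_proportions, n_fragments,
                               ambiguity_rate = 0.3, score_gap = 5, seed = 1,
                               sam_path = tempfile(fileext = ".sam"),
                               read_length = 75L, base_score = 60L) {
  validate_annotation(loci, "locus_id")
  stopifnot(n_fragments >= 1, ambiguity_rate >= 0, ambiguity_rate <= 1,
            score_gap >= 0)
  if (!setequal(names(true_proportions), loci$locus_id))
    stop("true_proportions must be indexed by exactly the given locus ids")
  if (abs(sum(true_proportions) - 1) > 1e-9)
    stop("true_proportions must sum to 1")
  if (nrow(loci) < 2 && ambiguity_rate > 0)
    stop("ambiguity_rate > 0 requires at least 2 loci (no decoys possible)")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  chrom_lengths <- attr(loci, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(loci$end, loci$chrom, max) + 1000L
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }

  p <- true_proportions[loci$locus_id]
  true_idx <- sample.int(nrow(loci), n_fragments, replace = TRUE, prob = p)
  ambiguous <- stats::runif(n_fragments) < ambiguity_rate
  frag_id <- sprintf("frag%06d", seq_len(n_fragments))

  place_read <- function(idx) {
    len <- pmin(read_length, loci$end[idx] - loci$start[idx])
    off <- floor(stats::runif(length(idx)) * (loci$end[idx] - loci$start[idx] - len + 1))
    start0 <- loci$start[idx] + as.integer(off)
    list(pos = start0 + 1L, cigar = paste0(len, "M"))
  }

  tp <- place_read(true_idx)
  amb_i <- which(ambiguous)
  d_frag <- integer(0); d_locus <- integer(0)
  if (length(amb_i)) {
    nd <- pmin(sample(1:3, length(amb_i), replace = TRUE), nrow(loci) - 1L)
    for (k in seq_along(amb_i)) {
      d_frag <- c(d_frag, rep(amb_i[k], nd[k]))
      d_locus <- c(d_locus, sample(setdiff(seq_len(nrow(loci)), true_idx[amb_i[k]]),
                                   nd[k]))
    }
  }
  dp <- if (length(d_frag)) place_read(d_locus) else list(pos = integer(), cigar = character())
  recs <- data.frame(
    qname = c(frag_id, frag_id[d_frag]),
    flag = c(rep(0L, n_fragments), rep(256L, length(d_frag))),
    rname = c(loci$chrom[true_idx], loci$chrom[d_locus]),
    pos = c(tp$pos, dp$pos),
    cigar = c(tp$cigar, dp$cigar),
    score = c(rep(base_score, n_fragments),
              base_score - stats::rpois(length(d_frag), score_gap)),
    stringsAsFactors = FALSE
  )
  recs <- recs[order(recs$qname, recs$flag, recs$rname, recs$pos), , drop = FALSE]

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tAS:i:%d",
                  recs$qname, recs$flag, recs$rname, recs$pos,
                  ifelse(recs$flag == 0L, 60L, 0L), recs$cigar, recs$score)
  writeLines(c(header, body), sam_path)

  list(sam = sam_path,
       truth = data.frame(fragment_id = frag_id,
                          true_locus = loci$locus_id[true_idx],
                          ambiguous = ambiguous, stringsAsFactors = FALSE),
       sim_truth = list(true_proportions = p, seed = seed))
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts for feature i in sample j are drawn NB with mean
#' `baseline_i * 2^(lfc_i * case_j) * batch_factor_{b_j,i} *
#' library_size_factor_j` and the given dispersion. A fraction `frac_de` of
#' features receives a log2 fold change of `+/-lfc_magnitude` (random sign).
#' Batch effects are multiplicative per feature: in every non-reference batch
#' each feature is shifted by `2^(+batch_log2_shift)` or
#' `2^(-batch_log2_shift)` with a per-feature random sign, so the batch
#' signal is a genuine multivariate structure rather than a global scaling
#' that library-size normalization would absorb.
#'
#' @param design data.frame of samples (`sample_id`, `condition`, `batch`,
#'   optional `library_size_factor`).
#' @param n_features number of features.
#' @param frac_de fraction of features with a planted condition effect.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param batch_log2_shift absolute per-feature log2 batch shift for
#'   non-reference batches (0 disables batch effects).
#' @param seed integer seed.
#' @param baseline_range range of per-feature baseline means, sampled
#'   log-uniformly.
#' @param feature_prefix prefix for generated feature ids.
#' @return List with `matrix` (a [count_matrix()]) and `truth`: a list with
#'   `true_log2fc`, `true_de_set`, `batch_factor` (features x batches matrix
#'   of multiplicative factors), `baseline` and `seed`.
#' @export
simulate_counts <- function(design, n_features, frac_de = 0.1,
                            lfc_magnitude = 1, dispersion = 0.1,
                            batch_log2_shift = 0, seed = 1,
                            baseline_range = c(50, 500),
                            feature_prefix = "FEAT") {
  stopifnot(is.data.frame(design), n_features >= 1, dispersion > 0)
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  tab <- table(design$condition)
  if (!all(c("case", "control") %in% names(tab)) || any(tab < 2))
    stop("design needs >= 2 samples in each of 'case' and 'control'")
  if (is.null(design$library_size_factor)) design$library_size_factor <- 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  fid <- sprintf("%s%04d", feature_prefix, seq_len(n_features))
  baseline <- exp(stats::runif(n_features, log(baseline_range[1]),
                               log(baseline_range[2])))
  n_de <- as.integer(round(frac_de * n_features))
  de_idx <- if (n_de > 0) sample.int(n_features, n_de) else integer()
  lfc <- numeric(n_features)
  lfc[de_idx] <- lfc_magnitude * sample(c(-1, 1), n_de, replace = TRUE)

  batches <- unique(design$batch)
  batch_factor <- matrix(1, n_features, length(batches),
                         dimnames = list(fid, batches))
  if (batch_log2_shift != 0 && length(batches) > 1) {
    for (b in batches[-1]) {
      sgn <- sample(c(-1, 1), n_features, replace = TRUE)
      batch_factor[, b] <- 2^(batch_log2_shift * sgn)
    }
  }

  is_case <- as.numeric(design$condition == "case")
  mu <- outer(baseline, design$library_size_factor) *
    2^(outer(lfc, is_case)) *
    batch_factor[, match(design$batch, batches), drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_features, nrow(design),
                   dimnames = list(fid, design$sample_id))

  list(matrix = count_matrix(counts, design),
       truth = list(true_log2fc = stats::setNames(lfc, fid),
                    true_de_set = fid[de_idx],
                    batch_factor = batch_factor,
                    baseline = stats::setNames(baseline, fid),
                    seed = seed))
}

#' Build a balanced case/control, multi-batch sample design
#'
#' Convenience constructor for the two-condition, multi-batch layouts the
#' simulators consume. Conditions are balanced within every batch so batch is
#' never confounded with condition.
#'
#' @param n_per_group samples per condition.
#' @param n_batches number of batches conditions are spread across.
#' @param libsize_range range of library-size factors, sampled log-uniformly
#'   (use `c(1, 1)` for equal depths).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `condition`, `batch`,
#'   `library_size_factor`.
#' @export
make_design <- function(n_per_group, n_batches = 1, libsize_range = c(1, 1),
                        seed = 1) {
  stopifnot(n_per_group >= 2, n_batches >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cond <- rep(c("control", "case"), each = n_per_group)
  batch <- paste0("B", rep_len(seq_len(n_batches), n_per_group))
  data.frame(
    sample_id = sprintf("S%03d", seq_len(2 * n_per_group)),
    condition = cond,
    batch = c(batch, batch),
    library_size_factor = exp(stats::runif(2 * n_per_group,
                                           log(libsize_range[1]),
                                           log(libsize_range[2]))),
    stringsAsFactors = FALSE
  )
}

#' Sample toy pathway gene sets and write them as GMT
#'
#' @param genes gene annotation data.frame.
#' @param n_pathways number of pathways.
#' @param size_range integer pair (min, max) of pathway sizes; genes are
#'   sampled without replacement within a pathway.
#' @param seed integer seed.
#' @param path output GMT path.
#' @return Named list of gene sets (invisibly written to `path`).
#' @export
make_pathway_db <- function(genes, n_pathways, size_range = c(5, 20), seed = 1,
                            path = tempfile(fileext = ".gmt")) {
  stopifnot(n_pathways >= 1)
  if (size_range[1] > size_range[2]) stop("size_range must be (min, max) with min <= max")
  if (size_range[2] > nrow(genes))
    stop("max pathway size exceeds number of genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sizes <- if (size_range[1] == size_range[2]) rep(size_range[1], n_pathways)
           else sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes$gene_id, k))
  names(sets) <- sprintf("PWY%03d", seq_len(n_pathways))
  write_gmt(sets, path, descriptions = sprintf("toy pathway %d", seq_len(n_pathways)))
  attr(sets, "path") <- path
  sets
}

#' Pick a toy interferon-signature gene set
#'
#' Samples `n` gene ids to serve as the planted immune signature for the
#' correlation analyses.
#'
#' @param genes gene annotation data.frame.
#' @param n signature size.
#' @param seed integer seed.
#' @return Character vector of gene ids.
#' @export
toy_signature_genes <- function(genes, n = 10, seed = 1) {
  stopifnot(n >= 1, n <= nrow(genes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(genes$gene_id, n)
}
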