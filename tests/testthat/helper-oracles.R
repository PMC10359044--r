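# Independent oracles and small fixture builders shared across tests.

# Dense grid search over the probability simplex for the penalized mixture
# log-likelihood: sum_f log(sum_k pi_k L[f,k]) + sum_k theta * log(pi_k).
# L is a dense fragments x K candidate-likelihood matrix (0 = non-candidate).
# Independent of the EM implementation.
grid_search_pi <- function(L, theta, step = 1e-3) {
  K <- ncol(L)
  stopifnot(K %in% c(2, 3))
  g <- seq(0, 1, by = step)
  if (K == 2) {
    P <- cbind(g, 1 - g)
  } else {
    gg <- expand.grid(p1 = g, p2 = g)
    gg <- gg[gg$p1 + gg$p2 <= 1 + 1e-12, ]
    P <- cbind(gg$p1, gg$p2, pmax(1 - gg$p1 - gg$p2, 0))
  }
  mix <- P %*% t(L)                      # n_grid x n_fragments
  ll <- rowSums(log(mix))
  if (theta > 0) {
    ll <- ll + theta * rowSums(log(P))   # -Inf on the boundary, as intended
  }
  unname(P[which.max(ll), ])
}

# Random tiny EM instance: <= 3 loci, <= 5 fragments, every fragment has at
# least one candidate locus. Returns the fragment_assignments object and the
# dense likelihood matrix matching the package's score -> likelihood map.
random_em_instance <- function(seed, score_scale = 10) {
  set.seed(seed)
  K <- sample(2:3, 1)
  nf <- sample(2:5, 1)
  entries <- do.call(rbind, lapply(seq_len(nf), function(f) {
    cand <- sort(sample(seq_len(K), sample(seq_len(K), 1)))
    data.frame(fragment = sprintf("f%d", f),
               locus = LETTERS[cand],
               score = round(runif(length(cand), 30, 60), 1))
  }))
  fam <- fragment_assignments(entries)
  L <- matrix(0, length(fam$fragment_ids), length(fam$locus_ids),
              dimnames = list(fam$fragment_ids, fam$locus_ids))
  sm <- as.matrix(fam$score)
  cm <- as.matrix(fam$candidate)
  for (i in seq_len(nrow(L))) {
    cand <- cm[i, ] > 0
    L[i, cand] <- exp((sm[i, cand] - max(sm[i, cand])) / score_scale)
  }
  list(fam = fam, L = L)
}

# Brute-force Benjamini-Hochberg step-up from its definition:
# q_(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back to input order.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# All-pairs proximal-gene scan: for one locus, examine every gene directly.
proximal_brute_force <- function(loci, genes) {
  res <- lapply(seq_len(nrow(loci)), function(i) {
    g <- genes[genes$chrom == loci$chrom[i], , drop = FALSE]
    ls <- loci$start[i]; le <- loci$end[i]
    inter <- character(0); up <- NA_character_; ud <- NA_real_
    dn <- NA_character_; dd <- NA_real_
    for (k in seq_len(nrow(g))) {
      if (g$start[k] < le && g$end[k] > ls) inter <- c(inter, g$gene_id[k])
      if (g$end[k] <= ls) {
        d <- ls - g$end[k]
        if (is.na(ud) || d < ud || (d == ud && g$gene_id[k] < up)) {
          up <- g$gene_id[k]; ud <- d
        }
      }
      if (g$start[k] >= le) {
        d <- g$start[k] - le
        if (is.na(dd) || d < dd || (d == dd && g$gene_id[k] < dn)) {
          dn <- g$gene_id[k]; dd <- d
        }
      }
    }
    data.frame(herv_id = loci$locus_id[i],
               upstream_gene = up, upstream_dist = ud,
               downstream_gene = dn, downstream_dist = dd,
               intersecting = paste(sort(inter), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Textbook Pearson r and its t-based p-value, written out longhand.
pearson_brute_force <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Minimal two-locus annotation on one toy chromosome, for SAM round trips.
two_locus_annotation <- function() {
  ann <- data.frame(
    locus_id = c("HML2_1q1", "MER101_1q2"),
    chrom = "chr1",
    start = c(1000L, 5000L),
    end = c(2000L, 6000L),
    strand = c("+", "-"),
    family = c("HML2", "MER101"),
    stringsAsFactors = FALSE
  )
  attr(ann, "chrom_lengths") <- c(chr1 = 1000000L)
  ann
}

# Write a SAM file from a record data.frame (qname, flag, rname, pos, cigar,
# score), with @SQ lines for the given chromosome lengths.
write_test_sam <- function(recs, chrom_lengths, path = tempfile(fileext = ".sam"),
                           as_tag = TRUE) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  tag <- if (as_tag) sprintf("\tAS:i:%d", recs$score) else ""
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
                  recs$qname, recs$flag, recs$rname, recs$pos, recs$cigar, tag)
  writeLines(c(header, body), path)
  path
}
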