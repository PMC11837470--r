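#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (ties get the average rank);
#' the enrichment score is the summed difference between the weighted ECDF
#' of in-set genes (weights = rank^alpha) and the uniform ECDF of out-of-set
#' genes, walking the list from the highest-ranked gene down. Scores are
#' normalized by the range (max - min) over the whole score matrix. Being
#' rank-based, scores are invariant to strictly monotone transforms of a
#' sample's expression.
#'
#' @param expr expression matrix (genes x samples).
#' @param sets named list of gene identifier vectors.
#' @param alpha rank-weight exponent.
#' @return matrix of normalized scores, sets x samples.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25) {
  validate_expression(expr)
  genes <- rownames(expr)
  sets_m <- lapply(sets, intersect, y = genes)
  drop <- vapply(sets_m, length, 1L) < 2
  if (any(drop)) {
    warning("skipping set(s) with < 2 measured genes: ",
            paste(names(sets)[drop], collapse = ", "))
    sets_m <- sets_m[!drop]
  }
  if (!length(sets_m)) stop("no usable gene set")
  n <- length(genes)
  es <- matrix(NA_real_, length(sets_m), ncol(expr),
               dimnames = list(names(sets_m), colnames(expr)))
  inset_idx <- lapply(sets_m, function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j])                      # ties -> average rank
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    for (i in seq_along(sets_m)) {
      ins <- inset_idx[[i]][ord]
      win <- w * ins
      cum_in <- cumsum(win) / sum(win)
      cum_out <- cumsum(!ins) / sum(!ins)
      es[i, j] <- sum(cum_in - cum_out)
    }
  }
  rng <- max(es) - min(es)
  if (rng > 0) es <- es / rng
  es
}

#' Mean z-score of a gene set per sample
#'
#' Genes are standardized across samples (constant genes dropped); the score
#' is the mean z over the set's measured genes.
#'
#' @param expr expression matrix.
#' @param set character vector of genes.
#' @return named numeric vector, one score per sample.
#' @export
signature_zscore <- function(expr, set) {
  validate_expression(expr)
  genes <- intersect(set, rownames(expr))
  if (!length(genes)) stop("no gene of the set is measured")
  if (length(genes) < length(set))
    warning(length(set) - length(genes), " set gene(s) not measured")
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  z <- t(scale(t(sub)))
  colMeans(z)
}

#' Nonsilent variant classes counted for mutation burden
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Tumor mutation burden (mutations per megabase)
#'
#' @param maf MAF data.frame from [read_maf()] or [simulate_maf()].
#' @param capture_mb captured genome size in Mb (exome default 38).
#' @param classes variant classes counted as nonsilent.
#' @param include_unknown count classes outside [maf_classes()] too.
#' @param samples optional sample universe (zero-burden samples included).
#' @return named numeric vector, mutations/Mb per sample.
#' @export
tmb <- function(maf, capture_mb = 38, classes = nonsilent_classes(),
                include_unknown = FALSE, samples = NULL) {
  if (capture_mb <= 0) stop("capture_mb must be > 0")
  unknown <- setdiff(unique(maf$Variant_Classification), maf_classes())
  if (length(unknown) && !include_unknown)
    warning("excluding unknown class(es): ", paste(unknown, collapse = ", "))
  keep <- maf$Variant_Classification %in% classes |
    (include_unknown & maf$Variant_Classification %in% unknown)
  if (is.null(samples)) samples <- unique(maf$Tumor_Sample_Barcode)
  counts <- table(factor(maf$Tumor_Sample_Barcode[keep], levels = samples))
  stats::setNames(as.numeric(counts) / capture_mb, samples)
}

#' Fraction of genome altered, gained and lost
#'
#' Per sample, the denominator is the total profiled length (sum of segment
#' lengths); FGG is the length fraction with log2 ratio >= `thresh`, FGL the
#' fraction <= `-thresh`, and FGA = FGG + FGL under this symmetric
#' threshold.
#'
#' @param seg SEG data.frame.
#' @param thresh absolute log2-ratio threshold.
#' @return data.frame: sample, FGA, FGG, FGL.
#' @export
cna_fractions <- function(seg, thresh = 0.2) {
  len <- seg$End - seg$Start + 1
  out <- do.call(rbind, lapply(split(seq_len(nrow(seg)), seg$Sample), function(i) {
    L <- sum(len[i])
    if (L == 0) {
      warning("sample with zero profiled length")
      return(data.frame(sample = seg$Sample[i[1L]], FGA = NA_real_,
                        FGG = NA_real_, FGL = NA_real_))
    }
    fgg <- sum(len[i][seg$Segment_Mean[i] >= thresh]) / L
    fgl <- sum(len[i][seg$Segment_Mean[i] <= -thresh]) / L
    data.frame(sample = seg$Sample[i[1L]], FGA = fgg + fgl, FGG = fgg,
               FGL = fgl, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Arm-level and focal copy-number event burden
#'
#' Each altered segment (|log2 ratio| >= `thresh`) is assigned to the arm it
#' overlaps most. Per arm and direction, if the total altered overlap covers
#' at least `arm_frac` of the arm, one arm-level event is counted; altered
#' segments on arms without an arm-level event in that direction each count
#' as one focal event.
#'
#' @param seg SEG data.frame.
#' @param arm_table data.frame with chrom, arm, start, end.
#' @param thresh absolute log2-ratio threshold.
#' @param arm_frac arm coverage fraction for an arm-level call.
#' @return data.frame: sample, arm_gain, arm_loss, focal_gain, focal_loss.
#' @export
arm_focal_burden <- function(seg, arm_table = toy_arm_table(), thresh = 0.2,
                             arm_frac = 0.5) {
  alt <- seg[abs(seg$Segment_Mean) >= thresh, , drop = FALSE]
  samples <- unique(seg$Sample)
  res <- data.frame(sample = samples, arm_gain = 0L, arm_loss = 0L,
                    focal_gain = 0L, focal_loss = 0L, stringsAsFactors = FALSE)
  if (!nrow(alt)) return(res)
  arm_len <- arm_table$end - arm_table$start + 1
  for (si in seq_along(samples)) {
    rows <- which(alt$Sample == samples[si])
    if (!length(rows)) next
    assigned_arm <- integer(length(rows))
    overlap_len <- numeric(length(rows))
    for (r in seq_along(rows)) {
      i <- rows[r]
      cand <- which(arm_table$chrom == alt$Chromosome[i])
      ov <- pmax(0, pmin(alt$End[i], arm_table$end[cand]) -
                   pmax(alt$Start[i], arm_table$start[cand]) + 1)
      if (!length(cand) || max(ov) == 0) {
        warning("segment with no arm overlap ignored")
        assigned_arm[r] <- NA_integer_
        next
      }
      assigned_arm[r] <- cand[which.max(ov)]
      overlap_len[r] <- max(ov)
    }
    dir <- ifelse(alt$Segment_Mean[rows] > 0, "gain", "loss")
    for (dd in c("gain", "loss")) {
      sel <- which(dir == dd & !is.na(assigned_arm))
      if (!length(sel)) next
      per_arm <- tapply(overlap_len[sel], assigned_arm[sel], sum)
      arm_hit <- as.integer(names(per_arm))[per_arm >=
                                              arm_frac * arm_len[as.integer(names(per_arm))]]
      n_arm <- length(arm_hit)
      n_focal <- sum(!(assigned_arm[sel] %in% arm_hit))
      if (dd == "gain") {
        res$arm_gain[si] <- n_arm; res$focal_gain[si] <- n_focal
      } else {
        res$arm_loss[si] <- n_arm; res$focal_loss[si] <- n_focal
      }
    }
  }
  res
}

#' Tally SNVs into the 96 trinucleotide substitution contexts
#'
#' Uses the MAF's `ref_context` trinucleotide column. Purine-reference rows
#' are collapsed to the pyrimidine strand (alleles complemented, context
#' reverse-complemented). Indels and rows without a valid context are
#' skipped (counts reported via attributes `n_indel` / `n_skipped`).
#'
#' @param maf MAF data.frame with `ref_context`.
#' @return integer matrix, samples x 96 contexts.
#' @export
context96_tally <- function(maf) {
  if (is.null(maf$ref_context)) stop("MAF lacks a ref_context column")
  labels <- context96_labels()
  ref <- as.character(maf$Reference_Allele)
  alt <- as.character(maf$Tumor_Seq_Allele2)
  tri <- toupper(as.character(maf$ref_context))
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") & ref != alt
  n_indel <- sum(!is_snv)
  has_ctx <- nchar(tri) == 3 & !is.na(tri) & substr(tri, 2, 2) == ref
  n_skipped <- sum(is_snv & !has_ctx)
  if (n_skipped) warning(n_skipped, " SNV row(s) without valid ref_context skipped")
  use <- is_snv & has_ctx
  ref <- ref[use]; alt <- alt[use]; tri <- tri[use]
  flip <- ref %in% c("A", "G")
  ref[flip] <- .comp(ref[flip]); alt[flip] <- .comp(alt[flip])
  tri[flip] <- .revcomp(tri[flip])
  channel <- sprintf("%s[%s>%s]%s", substr(tri, 1, 1), ref, alt,
                     substr(tri, 3, 3))
  samples <- unique(maf$Tumor_Sample_Barcode)
  out <- table(factor(maf$Tumor_Sample_Barcode[use], levels = samples),
               factor(channel, levels = labels))
  out <- matrix(as.integer(out), nrow = length(samples),
                dimnames = list(samples, labels))
  attr(out, "n_indel") <- n_indel
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fit mutational-signature exposures by nonnegative least squares
#'
#' Solves min ||M e - c||_2 subject to e >= 0 per sample, where M is the
#' reference matrix (96 contexts x signatures, columns summing to 1) and c
#' the sample's context counts; exposures are normalized to proportions.
#'
#' @param counts samples x 96 matrix from [context96_tally()].
#' @param reference 96 x signatures reference matrix.
#' @return list with `exposures` (samples x signatures, rows sum to 1 where
#'   mutations exist) and `residual` (per-sample residual norm).
#' @export
fit_exposures <- function(counts, reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) != 96) stop("reference must have 96 rows")
  if (any(abs(colSums(reference) - 1) > 1e-6))
    stop("reference signature columns must sum to 1")
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  expo <- matrix(0, nrow(counts), ncol(reference),
                 dimnames = list(rownames(counts), colnames(reference)))
  resid <- stats::setNames(numeric(nrow(counts)), rownames(counts))
  for (i in seq_len(nrow(counts))) {
    c_i <- counts[i, ]
    if (sum(c_i) == 0) { resid[i] <- 0; next }
    fit <- pracma::lsqnonneg(reference, c_i)
    e <- fit$x
    resid[i] <- sqrt(sum((reference %*% e - c_i)^2))
    if (sum(e) > 0) e <- e / sum(e)
    expo[i, ] <- e
  }
  list(exposures = expo, residual = resid)
}
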