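#' Ground truth for a synthetic cell-line drug-response panel
#'
#' Describes, per drug, the lognormal IC50 distribution (micromolar), and,
#' per planted effect gene, its direction and effect size in log2 units.
#' Effect genes are assigned round-robin to drugs; each responds to the
#' standardized log10 IC50 of its drug. Defaults emulate a micromolar-range
#' panel of the seven chemotherapeutics used for consensus feature discovery.
#'
#' @param drugs character vector of drug names.
#' @param n_genes total genes on the panel.
#' @param n_effect number of planted effect genes (strict subset of genes).
#' @param effect_size per-gene effect magnitude, log2 units.
#' @param meanlog,sdlog lognormal IC50 parameters (log micromolar), recycled
#'   over drugs.
#' @return list describing the panel truth.
#' @export
cell_panel_truth <- function(drugs = c("5-fluorouracil", "cisplatin",
                                       "epirubicin", "gemcitabine",
                                       "irinotecan", "olaparib", "oxaliplatin"),
                             n_genes = 500, n_effect = 40, effect_size = 1,
                             meanlog = 0, sdlog = 1) {
  stopifnot(n_effect < n_genes, all(sdlog > 0))
  genes <- sprintf("G%04d", seq_len(n_genes))
  eff <- genes[seq_len(n_effect)]
  direction <- rep(c("up_in_resistant", "up_in_sensitive"), length.out = n_effect)
  list(
    drugs = drugs,
    ic50_meanlog = stats::setNames(rep(meanlog, length.out = length(drugs)), drugs),
    ic50_sdlog = stats::setNames(rep(sdlog, length.out = length(drugs)), drugs),
    genes = genes,
    effect_genes = eff,
    effect_direction = stats::setNames(direction, eff),
    effect_drug = stats::setNames(rep(drugs, length.out = n_effect), eff),
    effect_size = stats::setNames(rep(effect_size, length.out = n_effect), eff)
  )
}

#' Simulate a cell-line pharmacogenomic panel
#'
#' IC50 is drawn lognormal per drug; EC50 = IC50 * u with u ~ Uniform(0.5, 1);
#' log10 forms are derived. Expression is a per-gene baseline N(6, 1) plus,
#' for effect genes, the effect size times the standardized log10 IC50 of the
#' assigned drug (positive for genes up in resistant lines, negative for
#' genes up in sensitive lines), plus N(0, noise_sd) noise. `noise_sd = 0`
#' gives the noiseless mode used for exact-recovery tests.
#'
#' @param n_lines number of cell lines (>= 10).
#' @param truth a [cell_panel_truth()] object.
#' @param seed integer seed; output is deterministic given the seed.
#' @param database database label attached to the response table.
#' @param noise_sd expression noise SD (log2 units).
#' @return list with `response` (data.frame: cell_line, drug, IC50,
#'   log10_IC50, EC50, log10_EC50, database), `expr` (genes x lines matrix)
#'   and `truth`.
#' @export
simulate_cellline_panel <- function(n_lines, truth = cell_panel_truth(),
                                    seed = 1, database = "DB1",
                                    noise_sd = 0.5) {
  if (n_lines < 10) stop("n_lines must be >= 10 for grouping")
  if (any(truth$ic50_sdlog[unique(truth$effect_drug)] <= 0))
    stop("drug with zero IC50 variance cannot carry planted effects")
  set.seed(as.integer(seed))
  lines <- sprintf("%s_CL%03d", database, seq_len(n_lines))
  drugs <- truth$drugs
  resp <- do.call(rbind, lapply(drugs, function(d) {
    ic50 <- stats::rlnorm(n_lines, truth$ic50_meanlog[d], truth$ic50_sdlog[d])
    ec50 <- ic50 * stats::runif(n_lines, 0.5, 1)
    data.frame(cell_line = lines, drug = d, IC50 = ic50,
               log10_IC50 = log10(ic50), EC50 = ec50,
               log10_EC50 = log10(ec50), database = database,
               stringsAsFactors = FALSE)
  }))
  base <- stats::rnorm(length(truth$genes), 6, 1)
  expr <- matrix(base, nrow = length(truth$genes), ncol = n_lines)
  dimnames(expr) <- list(truth$genes, lines)
  for (g in truth$effect_genes) {
    d <- truth$effect_drug[[g]]
    z <- scale(resp$log10_IC50[resp$drug == d])[, 1L]
    sgn <- if (truth$effect_direction[[g]] == "up_in_resistant") 1 else -1
    expr[g, ] <- expr[g, ] + sgn * truth$effect_size[[g]] * z
  }
  if (noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd), nrow(expr))
  validate_expression(expr)
  list(response = resp, expr = expr, truth = truth)
}

#' Ground truth for a synthetic patient cohort
#'
#' Three expression subtypes with planted marker blocks that double as
#' co-expression modules (block genes share a latent factor), subtype-
#' dependent exponential survival hazards, and subtype-dependent mutation
#' and copy-number burden. Default hazards give median overall survival of
#' about 8, 16 and 32 months for subtypes 1, 2 and 3, mirroring a poor /
#' intermediate / favorable prognosis ordering.
#'
#' @param proportions subtype mixing proportions (length 3, sums to 1).
#' @param marker_size genes per subtype marker block.
#' @param shift subtype mean shift on marker blocks, log2 units.
#' @param module_cor target within-module pairwise correlation.
#' @param noise_sd residual expression noise SD (log2 units).
#' @param hazards per-subtype exponential hazard, 1/day.
#' @param censor_rate probability a sample is censored.
#' @param mutation_rates per-subtype mean nonsilent mutation count.
#' @param cna_burden per-subtype expected altered genome fraction.
#' @return list describing the cohort truth.
#' @export
cohort_truth <- function(proportions = c(1, 1, 1) / 3, marker_size = 40,
                         shift = 1.5, module_cor = 0.6, noise_sd = 0.5,
                         hazards = log(2) / c(240, 480, 960),
                         censor_rate = 0.2,
                         mutation_rates = c(60, 35, 25),
                         cna_burden = c(0.35, 0.15, 0.1)) {
  stopifnot(length(proportions) == 3, abs(sum(proportions) - 1) < 1e-8,
            all(hazards > 0), censor_rate >= 0, censor_rate < 1,
            module_cor > 0, module_cor < 1)
  list(proportions = proportions, marker_size = marker_size, shift = shift,
       module_cor = module_cor, noise_sd = noise_sd, hazards = hazards,
       censor_rate = censor_rate, mutation_rates = mutation_rates,
       cna_burden = cna_burden)
}

#' Simulate a patient expression cohort with survival
#'
#' Genes are organized as three subtype marker blocks followed by background
#' genes. Block genes share a per-sample latent factor whose loading is set
#' so the within-block pairwise correlation matches `truth$module_cor` given
#' the noise SD; samples of the matching subtype get an additional mean
#' shift. Survival times are exponential with the subtype's hazard;
#' censoring is independent: with probability `censor_rate` a sample is
#' censored at a Uniform(0, T) fraction of its event time. `noiseless = TRUE`
#' sets the noise SD and censoring to zero for exact-recovery tests.
#'
#' @param n_samples number of samples (>= 30).
#' @param n_genes total genes (>= 3 * marker block size).
#' @param truth a [cohort_truth()] object.
#' @param seed integer seed.
#' @param cohort cohort label for the clinical table.
#' @param noiseless logical; exact mode.
#' @return list with `expr`, `clinical` (sample/time/event/cohort),
#'   `labels` (named integer subtype per sample), `marker_genes` (list of
#'   3 character vectors) and `truth`.
#' @export
simulate_patient_cohort <- function(n_samples, n_genes = 300,
                                    truth = cohort_truth(), seed = 1,
                                    cohort = "SYN", noiseless = FALSE) {
  if (n_samples < 30) stop("n_samples must be >= 30")
  if (3L * truth$marker_size > n_genes)
    stop("marker blocks exceed n_genes")
  set.seed(as.integer(seed))
  noise_sd <- if (noiseless) 0 else truth$noise_sd
  censor_rate <- if (noiseless) 0 else truth$censor_rate
  samples <- sprintf("%s_S%03d", cohort, seq_len(n_samples))
  counts <- floor(truth$proportions * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    frac <- truth$proportions * n_samples - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  labels <- sample(rep(1:3, counts))
  names(labels) <- samples
  genes <- sprintf("G%04d", seq_len(n_genes))
  marker_genes <- lapply(1:3, function(k)
    genes[(k - 1L) * truth$marker_size + seq_len(truth$marker_size)])
  base <- stats::rnorm(n_genes, 6, 1)
  expr <- matrix(base, n_genes, n_samples, dimnames = list(genes, samples))
  # Within-block pairwise correlation targets module_cor in total: the
  # subtype shift already contributes shift^2 * p(1-p) of shared variance,
  # and the latent factor supplies the remainder (floored at zero).
  target_shared <- noise_sd^2 * truth$module_cor / (1 - truth$module_cor)
  for (k in 1:3) {
    p_k <- truth$proportions[k]
    shift_var <- truth$shift^2 * p_k * (1 - p_k)
    lambda <- if (noise_sd > 0) sqrt(max(0, target_shared - shift_var)) else 1
    f <- stats::rnorm(n_samples)
    idx <- match(marker_genes[[k]], genes)
    expr[idx, ] <- expr[idx, ] +
      matrix(lambda * f, truth$marker_size, n_samples, byrow = TRUE) +
      truth$shift * matrix(as.numeric(labels == k), truth$marker_size,
                           n_samples, byrow = TRUE)
  }
  if (noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd), n_genes)
  t_event <- stats::rexp(n_samples, truth$hazards[labels])
  censored <- stats::runif(n_samples) < censor_rate
  time <- ifelse(censored, t_event * stats::runif(n_samples), t_event)
  time <- pmax(time, 1e-3)
  clinical <- data.frame(sample = samples, time = time,
                         event = as.integer(!censored), cohort = cohort,
                         stringsAsFactors = FALSE)
  validate_expression(expr)
  list(expr = expr, clinical = clinical, labels = labels,
       marker_genes = marker_genes, truth = truth)
}

#' The 96 trinucleotide substitution context labels
#'
#' Pyrimidine-strand convention: `X[R>A]Y` with R in C/T.
#' @return character vector of length 96.
#' @export
context96_labels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (f in bases) for (t in bases)
    out <- c(out, sprintf("%s[%s]%s", f, s, t))
  out
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), ""))
}
.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Simulate a mutation (MAF) table with trinucleotide contexts
#'
#' Per sample the nonsilent mutation count is Poisson with the subtype's
#' rate (or, in `exact` mode, the rate rounded to an integer). Contexts are
#' drawn from the supplied 96-context mixture; in `exact` mode the context
#' counts follow the mixture by largest-remainder rounding instead of
#' multinomial sampling. Half of the emitted rows are written on the purine
#' strand (context and alleles complemented) to exercise pyrimidine-strand
#' collapsing downstream.
#'
#' @param labels named integer subtype per sample (1-based).
#' @param rates per-subtype Poisson mean mutation count (> 0).
#' @param contexts probability vector over [context96_labels()] (sums to 1),
#'   or a matrix with one column per subtype.
#' @param seed integer seed.
#' @param exact logical; deterministic counts and context composition.
#' @return MAF data.frame with a `ref_context` column.
#' @export
simulate_maf <- function(labels, rates, contexts = rep(1 / 96, 96), seed = 1,
                         exact = FALSE) {
  if (any(rates <= 0)) stop("mutation rates must be > 0")
  set.seed(as.integer(seed))
  ctx_labels <- context96_labels()
  if (is.null(dim(contexts))) contexts <- matrix(contexts, 96, 3)
  stopifnot(nrow(contexts) == 96)
  rows <- list()
  for (s in names(labels)) {
    k <- labels[[s]]
    n <- if (exact) as.integer(round(rates[k])) else stats::rpois(1L, rates[k])
    if (n == 0L) next
    p <- contexts[, k] / sum(contexts[, k])
    counts <- if (exact) {
      base_ct <- floor(n * p)
      rem <- n - sum(base_ct)
      if (rem > 0) {
        frac <- n * p - base_ct
        add <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base_ct[add] <- base_ct[add] + 1L
      }
      base_ct
    } else as.vector(stats::rmultinom(1L, n, p))
    idx <- rep(seq_len(96), counts)
    ctx <- ctx_labels[idx]
    five <- substr(ctx, 1, 1); ref <- substr(ctx, 3, 3)
    alt <- substr(ctx, 5, 5); three <- substr(ctx, 7, 7)
    tri <- paste0(five, ref, three)
    flip <- seq_along(idx) %% 2L == 0L
    ref[flip] <- .comp(ref[flip]); alt[flip] <- .comp(alt[flip])
    tri[flip] <- .revcomp(tri[flip])
    rows[[s]] <- data.frame(
      Tumor_Sample_Barcode = s,
      Hugo_Symbol = sprintf("MUT%03d", sample.int(500, length(idx), replace = TRUE)),
      Variant_Classification = "Missense_Mutation",
      Chromosome = as.character(sample.int(4, length(idx), replace = TRUE)),
      Start_Position = sample.int(1e8, length(idx), replace = TRUE),
      Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
      ref_context = tri, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(Tumor_Sample_Barcode = character(0),
                      Hugo_Symbol = character(0),
                      Variant_Classification = character(0),
                      Chromosome = character(0), Start_Position = numeric(0),
                      Reference_Allele = character(0),
                      Tumor_Seq_Allele2 = character(0),
                      ref_context = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Toy genome arm table
#'
#' Four chromosomes with p and q arms (1-based inclusive coordinates),
#' 740 Mb total, used by the SEG simulator and arm/focal burden scoring.
#' @return data.frame with chrom, arm, start, end.
#' @export
toy_arm_table <- function() {
  data.frame(
    chrom = rep(as.character(1:4), each = 2),
    arm = rep(c("p", "q"), 4),
    start = c(1, 60e6 + 1, 1, 50e6 + 1, 1, 40e6 + 1, 1, 30e6 + 1),
    end = c(60e6, 150e6, 50e6, 130e6, 40e6, 110e6, 30e6, 70e6),
    stringsAsFactors = FALSE)
}

#' Simulate a copy-number segment (SEG) table
#'
#' Each sample's profile tiles the toy genome arm-by-arm; an arm is altered
#' with probability equal to the subtype's burden, receiving a log2 ratio of
#' +0.3 or -0.3 (equal odds), and 0 otherwise, so the expected fraction of
#' genome altered equals the burden.
#'
#' @param labels named integer subtype per sample.
#' @param burden per-subtype expected altered genome fraction in `[0, 1)`.
#' @param genome arm table as from [toy_arm_table()].
#' @param seed integer seed.
#' @return SEG data.frame (Sample, Chromosome, Start, End, Segment_Mean).
#' @export
simulate_seg <- function(labels, burden, genome = toy_arm_table(), seed = 1) {
  stopifnot(all(burden >= 0), all(burden < 1))
  set.seed(as.integer(seed))
  rows <- lapply(names(labels), function(s) {
    k <- labels[[s]]
    altered <- stats::runif(nrow(genome)) < burden[k]
    sign <- sample(c(-1, 1), nrow(genome), replace = TRUE)
    data.frame(Sample = s, Chromosome = genome$chrom, Start = genome$start,
               End = genome$end,
               Segment_Mean = ifelse(altered, sign * 0.3, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
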