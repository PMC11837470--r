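#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-scale values with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames. All values must be finite.
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample identifiers and one row per gene, first
#' column the gene identifier. Duplicate gene rows are collapsed by keeping
#' the row with the highest mean expression (a common microarray convention).
#'
#' @param path file path.
#' @return validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  dat <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(dat) == 0L || ncol(dat) < 2L)
    stop("expression file is empty or has no sample columns: ", path)
  genes <- as.character(dat[[1L]])
  samples <- colnames(dat)[-1L]   # before [.data.frame mangles duplicates
  vals <- dat[, -1L, drop = FALSE]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   genes[bad[1L]], samples[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    keep <- unlist(lapply(split(seq_len(nrow(m)), genes), function(i)
      i[which.max(means[i])]), use.names = FALSE)
    m <- m[sort(keep), , drop = FALSE]
  }
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member...`. Duplicate members
#' within a set are removed; duplicate set names are an error.
#'
#' @param path file path.
#' @return named list of character vectors of gene identifiers, with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nms[i] <- f[1L]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    set <- members
    attr(set, "description") <- f[2L]
    out[[i]] <- set
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    d <- attr(sets[[n]], "description")
    if (is.null(d)) d <- n
    paste(c(n, d, as.character(sets[[n]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.maf_required <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification",
                   "Chromosome", "Start_Position", "Reference_Allele",
                   "Tumor_Seq_Allele2")

#' Known MAF variant classifications
#' @export
maf_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation", "Silent", "3'UTR", "5'UTR",
    "Intron", "IGR", "RNA", "3'Flank", "5'Flank")
}

.read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
}

.require_cols <- function(dat, cols, what) {
  miss <- setdiff(cols, colnames(dat))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}

#' Read a mutation annotation (MAF) table
#'
#' Minimal column set: Tumor_Sample_Barcode, Hugo_Symbol,
#' Variant_Classification, Chromosome, Start_Position, Reference_Allele,
#' Tumor_Seq_Allele2; optional ref_context (trinucleotide around the site).
#' Chromosome names are normalized by stripping any "chr" prefix. Extra
#' columns are ignored.
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_maf <- function(path) {
  dat <- .read_tsv(path)
  .require_cols(dat, .maf_required, "MAF")
  dat$Chromosome <- sub("^chr", "", as.character(dat$Chromosome))
  dat$Start_Position <- as.numeric(dat$Start_Position)
  if (any(is.na(dat$Start_Position)) || any(dat$Start_Position < 1))
    stop("MAF Start_Position must be numeric and >= 1")
  bad <- setdiff(unique(dat$Variant_Classification), maf_classes())
  if (length(bad))
    warning("MAF contains undocumented Variant_Classification: ",
            paste(bad, collapse = ", "))
  dat
}

#' Read a copy-number segment (SEG) table
#'
#' Required columns: Sample, Chromosome, Start, End, Segment_Mean
#' (log2 ratio). Coordinates are 1-based inclusive; `Start < End` is
#' enforced and per-sample segments must not overlap within a chromosome.
#'
#' @param path file path.
#' @return data.frame of segments.
#' @export
read_seg <- function(path) {
  dat <- .read_tsv(path)
  .require_cols(dat, c("Sample", "Chromosome", "Start", "End", "Segment_Mean"),
                "SEG")
  dat$Chromosome <- sub("^chr", "", as.character(dat$Chromosome))
  for (col in c("Start", "End", "Segment_Mean")) dat[[col]] <- as.numeric(dat[[col]])
  if (any(!is.finite(dat$Start)) || any(!is.finite(dat$End)))
    stop("SEG coordinates must be numeric")
  if (any(dat$Start >= dat$End))
    stop("SEG requires Start < End for every segment")
  for (key in split(seq_len(nrow(dat)),
                    paste(dat$Sample, dat$Chromosome, sep = "\r"))) {
    o <- key[order(dat$Start[key])]
    if (length(o) > 1L && any(dat$Start[o][-1L] <= dat$End[o][-length(o)]))
      stop("overlapping segments for sample ", dat$Sample[o[1L]],
           " chromosome ", dat$Chromosome[o[1L]])
  }
  dat
}

#' Read a clinical survival table
#'
#' Required columns: sample, time (days, > 0), event (0/1), cohort.
#'
#' @param path file path.
#' @return data.frame with columns sample, time, event, cohort.
#' @export
read_clinical <- function(path) {
  dat <- .read_tsv(path)
  .require_cols(dat, c("sample", "time", "event", "cohort"), "clinical table")
  dat$time <- as.numeric(dat$time)
  if (any(!is.finite(dat$time)) || any(dat$time <= 0))
    stop("clinical time must be positive")
  if (!all(dat$event %in% c(0, 1)))
    stop("clinical event must be 0 or 1")
  if (anyDuplicated(dat$sample))
    stop("duplicate sample in clinical table")
  dat[, c("sample", "time", "event", "cohort")]
}

#' Write simple tab-separated tables (MAF/SEG/clinical)
#' @param dat data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(dat, path) {
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge expression cohorts onto a common standardized gene space
#'
#' Restricts all matrices to their gene intersection, drops genes with zero
#' variance in any cohort, standardizes each gene to mean 0 / SD 1 within
#' each cohort (the implemented stand-in for batch correction) and
#' concatenates the samples.
#'
#' @param matrices list of expression matrices (genes x samples).
#' @param cohort_labels character vector, one label per matrix.
#' @return list with `expr` (merged matrix) and `cohort` (named vector
#'   mapping sample to cohort label).
#' @export
merge_cohorts <- function(matrices, cohort_labels) {
  stopifnot(length(matrices) >= 2L, length(cohort_labels) == length(matrices))
  lapply(matrices, validate_expression)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(genes)) stop("empty gene intersection across cohorts")
  mats <- lapply(matrices, function(m) m[genes, , drop = FALSE])
  sds <- vapply(mats, function(m) apply(m, 1L, stats::sd), numeric(length(genes)))
  keep <- if (length(genes) == 1L) all(sds > 0) else rowSums(sds == 0) == 0
  genes <- genes[keep]
  if (!length(genes)) stop("no gene has nonzero variance in every cohort")
  std <- lapply(mats, function(m) {
    m <- m[genes, , drop = FALSE]
    t(scale(t(m)))
  })
  merged <- do.call(cbind, std)
  cohort <- rep(cohort_labels, vapply(std, ncol, 1L))
  names(cohort) <- colnames(merged)
  validate_expression(merged)
  list(expr = merged, cohort = cohort)
}
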