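#' Expression dataset for a two-group array experiment
#'
#' The central container of the pipeline: a probe-by-sample intensity matrix
#' with parallel detection flags (Present/Marginal/Absent), a probe
#' annotation mapping probes to biotype (lncRNA or mRNA) and gene symbol,
#' and a two-group sample design with designated control and treatment
#' groups. Modelled on the light list classes used for array data elsewhere
#' (e.g. limma's `EList`).
#'
#' @param intensities numeric probe-by-sample matrix with probe ids as row
#'   names and sample ids as column names. Non-negative when
#'   `scale = "linear"`.
#' @param flags character matrix of the same dimensions with entries in
#'   `"P"`, `"M"`, `"A"`.
#' @param annotation data frame with columns `probe_id`, `biotype`
#'   (`"lncRNA"` or `"mRNA"`), `gene_symbol`, and optionally `locus`,
#'   covering every probe.
#' @param design data frame with columns `sample_id` and `group`, exactly two
#'   groups covering all samples.
#' @param scale `"linear"` (raw intensities) or `"log2"`.
#' @param control,treatment group labels designating the two groups. Defaults
#'   to the first and second group label in order of appearance.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `intensities`, `flags`, `annotation`, `design`, `scale`.
#' @export
expression_dataset <- function(intensities, flags, annotation, design,
                               scale = c("linear", "log2"),
                               control = NULL, treatment = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    lnc_abort("lncnet_dim_error", "intensities must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    lnc_abort("lncnet_dim_error", "intensities must carry probe and sample ids")
  flags <- as.matrix(flags)
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  annotation[] <- lapply(annotation, function(x) if (is.character(x)) trimws(x) else x)
  design[] <- lapply(design, function(x) if (is.character(x)) trimws(x) else x)

  groups <- unique(design$group)
  if (is.null(control)) control <- groups[1]
  if (is.null(treatment)) treatment <- setdiff(groups, control)[1]

  x <- structure(list(intensities = intensities, flags = flags,
                      annotation = annotation, design = design,
                      scale = scale, control = control,
                      treatment = treatment),
                 class = "expression_dataset")
  validate_expression_dataset(x)
  x
}

validate_expression_dataset <- function(x) {
  ints <- x$intensities; flags <- x$flags
  ann <- x$annotation; des <- x$design
  probes <- rownames(ints); samples <- colnames(ints)
  if (anyDuplicated(probes))
    lnc_abort("lncnet_duplicate_error", "duplicate probe id(s): %s",
              paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples))
    lnc_abort("lncnet_duplicate_error", "duplicate sample id(s): %s",
              paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!identical(dim(ints), dim(flags)))
    lnc_abort("lncnet_dim_error",
              "flag matrix is %d x %d but intensities are %d x %d",
              nrow(flags), ncol(flags), nrow(ints), ncol(ints))
  if (!is.null(rownames(flags)) && !identical(rownames(flags), probes))
    lnc_abort("lncnet_dim_error", "flag rows do not match probe order")
  if (!is.null(colnames(flags)) && !identical(colnames(flags), samples))
    lnc_abort("lncnet_dim_error", "flag columns do not match sample order")
  bad <- setdiff(unique(as.vector(flags)), c("P", "M", "A"))
  if (length(bad))
    lnc_abort("lncnet_flag_error", "unknown detection flag symbol(s): %s",
              paste(bad, collapse = ", "))
  if (!all(c("probe_id", "biotype", "gene_symbol") %in% names(ann)))
    lnc_abort("lncnet_annotation_error",
              "annotation needs columns probe_id, biotype, gene_symbol")
  missing_ann <- setdiff(probes, ann$probe_id)
  if (length(missing_ann))
    lnc_abort("lncnet_annotation_error",
              "annotation does not cover probe(s): %s",
              paste(utils::head(missing_ann, 5), collapse = ", "))
  bad_bt <- setdiff(unique(ann$biotype), c("lncRNA", "mRNA"))
  if (length(bad_bt))
    lnc_abort("lncnet_annotation_error", "unknown biotype(s): %s",
              paste(bad_bt, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(des)))
    lnc_abort("lncnet_design_error", "design needs columns sample_id, group")
  orphan <- setdiff(samples, des$sample_id)
  if (length(orphan))
    lnc_abort("lncnet_design_error", "sample(s) absent from design: %s",
              paste(orphan, collapse = ", "))
  groups <- unique(des$group)
  if (length(groups) != 2L)
    lnc_abort("lncnet_design_error",
              "design must define exactly two groups, found %d", length(groups))
  if (!all(c(x$control, x$treatment) %in% groups) || x$control == x$treatment)
    lnc_abort("lncnet_design_error",
              "control/treatment designation does not match design groups")
  if (any(!is.finite(ints)))
    lnc_abort("lncnet_value_error", "non-finite intensity value(s)")
  if (x$scale == "linear" && any(ints < 0))
    lnc_abort("lncnet_value_error",
              "negative intensity on linear scale")
  invisible(x)
}

#' @export
print.expression_dataset <- function(x, ...) {
  nb <- table(factor(x$annotation$biotype[match(rownames(x$intensities),
                                                x$annotation$probe_id)],
                     levels = c("lncRNA", "mRNA")))
  cat(sprintf("expression_dataset: %d probes (%d lncRNA, %d mRNA) x %d samples [%s scale]\n",
              nrow(x$intensities), nb[["lncRNA"]], nb[["mRNA"]],
              ncol(x$intensities), x$scale))
  grp <- group_samples(x)
  cat(sprintf("  control   '%s': %s\n", x$control,
              paste(grp$control, collapse = ", ")))
  cat(sprintf("  treatment '%s': %s\n", x$treatment,
              paste(grp$treatment, collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$intensities)

#' Sample ids of the control and treatment groups
#'
#' @param x an `expression_dataset`.
#' @return list with character vectors `control` and `treatment`, in the
#'   column order of the intensity matrix.
#' @export
group_samples <- function(x) {
  grp <- x$design$group[match(colnames(x$intensities), x$design$sample_id)]
  list(control = colnames(x$intensities)[grp == x$control],
       treatment = colnames(x$intensities)[grp == x$treatment])
}

#' Subset an expression dataset by probes
#'
#' @param x an `expression_dataset`.
#' @param probes character vector of probe ids (order preserved).
#' @return an `expression_dataset` restricted to `probes`.
#' @export
subset_probes <- function(x, probes) {
  missing <- setdiff(probes, rownames(x$intensities))
  if (length(missing))
    lnc_abort("lncnet_value_error", "unknown probe id(s): %s",
              paste(utils::head(missing, 5), collapse = ", "))
  expression_dataset(x$intensities[probes, , drop = FALSE],
                     x$flags[probes, , drop = FALSE],
                     x$annotation[x$annotation$probe_id %in% probes, ,
                                  drop = FALSE],
                     x$design, scale = x$scale,
                     control = x$control, treatment = x$treatment)
}

# biotype of each probe, in matrix row order
probe_biotypes <- function(x) {
  x$annotation$biotype[match(rownames(x$intensities), x$annotation$probe_id)]
}

probe_symbols <- function(x, probes = rownames(x$intensities)) {
  x$annotation$gene_symbol[match(probes, x$annotation$probe_id)]
}
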