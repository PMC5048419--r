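#' Read an expression dataset from tab-separated files
#'
#' Reads the four plain-text tables that make up a dataset: the intensity
#' matrix and the parallel detection-flag matrix (probes as rows, one header
#' row of sample ids, first column `probe_id`), the probe annotation table
#' (`probe_id`, `biotype`, `gene_symbol`, optional `locus`) and the sample
#' design table (`sample_id`, `group`). Leading `# key=value` comment lines
#' in the intensity file record the scale (`# scale=log2`); leading
#' `# control=` / `# treatment=` lines in the design file designate groups.
#' Row and column order are preserved from the files. LF and CRLF endings
#' are accepted; files are read as UTF-8.
#'
#' @param path_intensities,path_flags,path_annotation,path_design file paths.
#' @return a validated [expression_dataset].
#' @export
read_expression_tsv <- function(path_intensities, path_flags,
                                path_annotation, path_design) {
  meta <- read_meta_lines(path_intensities)
  scale <- if ("scale" %in% names(meta)) meta[["scale"]] else "linear"
  if (!scale %in% c("linear", "log2"))
    lnc_abort("lncnet_io_error", "unknown scale metadata '%s'", scale)

  read_mat <- function(path) {
    df <- read_tsv_checked(path, "probe_id")
    ids <- as.character(df$probe_id)
    m <- as.matrix(df[setdiff(names(df), "probe_id")])
    rownames(m) <- ids
    m
  }
  ints <- read_mat(path_intensities)
  storage.mode(ints) <- "double"
  flags <- read_mat(path_flags)
  if (!identical(dim(ints), dim(flags)) ||
      !identical(rownames(ints), rownames(flags)) ||
      !identical(colnames(ints), colnames(flags)))
    lnc_abort("lncnet_dim_error",
              "intensity and flag files disagree on probes/samples")

  ann <- read_tsv_checked(path_annotation,
                          c("probe_id", "biotype", "gene_symbol"))
  dmeta <- read_meta_lines(path_design)
  des <- read_tsv_checked(path_design, c("sample_id", "group"))
  ctrl <- if ("control" %in% names(dmeta)) dmeta[["control"]] else NULL
  trt <- if ("treatment" %in% names(dmeta)) dmeta[["treatment"]] else NULL

  expression_dataset(ints, flags, ann, des, scale = scale,
                     control = ctrl, treatment = trt)
}

#' Write an expression dataset as tab-separated files
#'
#' Inverse of [read_expression_tsv()]: writes `intensities.tsv`, `flags.tsv`,
#' `annotation.tsv` and `design.tsv` into `out_dir` such that reading them
#' back reproduces the dataset (intensities to 15 significant digits, all
#' orders preserved). Scale and group designations are recorded as leading
#' `#` metadata lines.
#'
#' @param x an [expression_dataset].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_expression_tsv <- function(x, out_dir) {
  validate_expression_dataset(x)
  if (nrow(x$intensities) == 0L)
    lnc_abort("lncnet_value_error", "refusing to write a dataset with no probes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(out_dir, "intensities.tsv"),
             flags = file.path(out_dir, "flags.tsv"),
             annotation = file.path(out_dir, "annotation.tsv"),
             design = file.path(out_dir, "design.tsv"))
  ints_df <- data.frame(probe_id = rownames(x$intensities),
                        as.data.frame(x$intensities),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(ints_df, paths[["intensities"]],
            comment_lines = paste0("scale=", x$scale))
  flags_df <- data.frame(probe_id = rownames(x$flags),
                         as.data.frame(x$flags),
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(flags_df, paths[["flags"]])
  write_tsv(x$annotation, paths[["annotation"]])
  write_tsv(x$design, paths[["design"]],
            comment_lines = c(paste0("control=", x$control),
                              paste0("treatment=", x$treatment)))
  invisible(paths)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. The collection universe is either
#' the union of all members (`universe = NULL`) or an explicitly supplied
#' symbol vector, in which case every member must be covered.
#'
#' @param path GMT file path.
#' @param kind `"term"` for functional term sets, `"tf_target"` for
#'   transcription-factor target sets.
#' @param universe optional explicit universe of gene symbols.
#' @param name collection name; defaults to the file name.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path, kind = c("term", "tf_target"), universe = NULL,
                     name = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    lnc_abort("lncnet_io_error", "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short))
    lnc_abort("lncnet_gmt_error", "GMT line %d has no members",
              which(short)[1])
  set_names <- vapply(fields, `[[`, character(1), 1L)
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- set_names
  gene_set_collection(name, kind, sets, universe = universe,
                      descriptions = stats::setNames(descriptions, set_names))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- collection$descriptions
  if (is.null(desc))
    desc <- stats::setNames(rep("na", length(collection$sets)),
                            names(collection$sets))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Tab-separated file with columns `sample`, `group`, `gene`, `ct`
#' (threshold cycles, strictly positive). Every sample carrying a target
#' measurement must also carry the reference gene.
#'
#' @param path file path.
#' @param reference_gene name of the endogenous reference; defaults to
#'   `"β-actin"`.
#' @param control,treatment group labels; by default `"control"`/
#'   `"treatment"` when present, otherwise first/second label in order of
#'   appearance.
#' @return a `qpcr_table`: data frame with attributes `reference_gene`,
#'   `control`, `treatment`.
#' @export
read_qpcr_table <- function(path, reference_gene = "β-actin",
                            control = NULL, treatment = NULL) {
  df <- read_tsv_checked(path, c("sample", "group", "gene", "ct"))
  qpcr_table(df, reference_gene = reference_gene,
             control = control, treatment = treatment)
}

#' Construct and validate a qPCR Ct table
#'
#' @param df data frame with columns `sample`, `group`, `gene`, `ct`.
#' @inheritParams read_qpcr_table
#' @return a validated `qpcr_table`.
#' @export
qpcr_table <- function(df, reference_gene = "β-actin",
                       control = NULL, treatment = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    lnc_abort("lncnet_io_error", "qPCR table missing column(s): %s",
              paste(miss, collapse = ", "))
  df <- df[need]
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    lnc_abort("lncnet_value_error", "Ct values must be finite and > 0")
  groups <- unique(df$group)
  if (length(groups) != 2L)
    lnc_abort("lncnet_design_error",
              "qPCR table must contain exactly two groups, found %d",
              length(groups))
  if (is.null(control))
    control <- if ("control" %in% groups) "control" else groups[1]
  if (is.null(treatment)) treatment <- setdiff(groups, control)[1]
  if (!all(c(control, treatment) %in% groups))
    lnc_abort("lncnet_design_error", "qPCR group designation mismatch")
  with_target <- unique(df$sample[df$gene != reference_gene])
  with_ref <- unique(df$sample[df$gene == reference_gene])
  unref <- setdiff(with_target, with_ref)
  if (length(unref))
    lnc_abort("lncnet_pairing_error",
              "sample(s) lack the reference gene '%s': %s", reference_gene,
              paste(unref, collapse = ", "))
  structure(df, class = c("qpcr_table", "data.frame"),
            reference_gene = reference_gene,
            control = control, treatment = treatment)
}

#' Write a qPCR Ct table as TSV
#'
#' @param x a `qpcr_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}
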