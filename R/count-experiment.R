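#' Probe count experiment container
#'
#' Bundles a probe-by-sample matrix of raw molecular counts with its probe
#' annotation and sample design tables, validating the cross-references
#' between the three. This is the input object for [normalize_counts()] and
#' the screen hit-calling pipeline.
#'
#' @param counts Integer matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids). All entries must be
#'   non-negative integers.
#' @param annotation Data frame with columns `probe_id`, `target_gene`,
#'   `probe_class` (one of `"endogenous"`, `"housekeeping"`,
#'   `"positive_spike"`, `"negative_spike"`, `"tag"`) and optionally
#'   `spike_level` (relative concentration; required for positive spikes and
#'   must be absent/`NA` otherwise).
#' @param design Data frame with columns `sample_id`, `perturbation_id`
#'   (`"control"` for control wells), `arm` (one of `"kinase"`, `"sirna"`,
#'   `"cohort"`, `"other"`) and `group` (free label such as
#'   `"control"` / `"perturbed"` / `"normal"` / `"tumor"`).
#'
#' @return An object of class `count_experiment`: a list with elements
#'   `counts` (integer matrix), `annotation` (tibble) and `design` (tibble).
#'
#' @details Screen arms (`"kinase"`, `"sirna"`) must contain at least one
#'   control sample (`perturbation_id == "control"`); cohort-style arms are
#'   exempt. Validation reports every offending probe or sample id, not just
#'   the first.
#'
#' @examples
#' counts <- matrix(c(5L, 7L, 0L, 2L, 100L, 90L), nrow = 3, byrow = TRUE,
#'                  dimnames = list(c("P1", "P2", "HK1"), c("s1", "s2")))
#' ann <- data.frame(probe_id = c("P1", "P2", "HK1"),
#'                   target_gene = c("G1", "G2", "PGK1"),
#'                   probe_class = c("endogenous", "endogenous", "housekeeping"))
#' des <- data.frame(sample_id = c("s1", "s2"),
#'                   perturbation_id = c("control", "pertA"),
#'                   arm = "sirna", group = c("control", "perturbed"))
#' ce <- count_experiment(counts, ann, des)
#' dim(ce$counts)
#' @export
count_experiment <- function(counts, annotation, design) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  annotation <- as_tibble(annotation)
  design <- as_tibble(design)

  need_ann <- c("probe_id", "target_gene", "probe_class")
  if (!all(need_ann %in% names(annotation))) {
    abort(sprintf("`annotation` must have columns: %s.", id_list(need_ann)))
  }
  need_des <- c("sample_id", "perturbation_id", "arm", "group")
  if (!all(need_des %in% names(design))) {
    abort(sprintf("`design` must have columns: %s.", id_list(need_des)))
  }
  if (!("spike_level" %in% names(annotation))) {
    annotation$spike_level <- NA_real_
  }

  problems <- character()
  if (anyDuplicated(annotation$probe_id)) {
    problems <- c(problems, sprintf(
      "duplicated probe ids in annotation: %s",
      id_list(unique(annotation$probe_id[duplicated(annotation$probe_id)]))))
  }
  if (anyDuplicated(design$sample_id)) {
    problems <- c(problems, sprintf(
      "duplicated sample ids in design: %s",
      id_list(unique(design$sample_id[duplicated(design$sample_id)]))))
  }

  classes <- c("endogenous", "housekeeping", "positive_spike", "negative_spike", "tag")
  bad_class <- setdiff(unique(annotation$probe_class), classes)
  if (length(bad_class)) {
    problems <- c(problems, sprintf("unknown probe_class values: %s", id_list(bad_class)))
  }
  arms <- c("kinase", "sirna", "cohort", "other")
  bad_arm <- setdiff(unique(design$arm), arms)
  if (length(bad_arm)) {
    problems <- c(problems, sprintf("unknown arm values: %s", id_list(bad_arm)))
  }

  # spike_level present iff positive spike
  is_pos <- annotation$probe_class == "positive_spike"
  miss_lvl <- annotation$probe_id[is_pos & !is.finite(annotation$spike_level)]
  if (length(miss_lvl)) {
    problems <- c(problems, sprintf(
      "positive_spike probes lacking spike_level: %s", id_list(miss_lvl)))
  }
  extra_lvl <- annotation$probe_id[!is_pos & is.finite(annotation$spike_level)]
  if (length(extra_lvl)) {
    problems <- c(problems, sprintf(
      "spike_level given for non-spike probes: %s", id_list(extra_lvl)))
  }
  if (any(is_pos) && any(annotation$spike_level[is_pos] <= 0, na.rm = TRUE)) {
    problems <- c(problems, "spike_level values must be > 0")
  }

  # cross references
  miss_ann <- setdiff(rownames(counts), annotation$probe_id)
  if (length(miss_ann)) {
    problems <- c(problems, sprintf(
      "probes in counts missing from annotation: %s", id_list(miss_ann)))
  }
  miss_cnt <- setdiff(annotation$probe_id, rownames(counts))
  if (length(miss_cnt)) {
    problems <- c(problems, sprintf(
      "annotated probes missing from counts: %s", id_list(miss_cnt)))
  }
  miss_des <- setdiff(colnames(counts), design$sample_id)
  if (length(miss_des)) {
    problems <- c(problems, sprintf(
      "samples in counts missing from design: %s", id_list(miss_des)))
  }
  miss_smp <- setdiff(design$sample_id, colnames(counts))
  if (length(miss_smp)) {
    problems <- c(problems, sprintf(
      "designed samples missing from counts: %s", id_list(miss_smp)))
  }

  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
    problems <- c(problems, sprintf(
      "counts must be non-negative integers; offending probes: %s",
      id_list(unique(rownames(counts)[bad[, 1L]]))))
  }

  screen_arms <- intersect(unique(design$arm), c("kinase", "sirna"))
  for (a in screen_arms) {
    in_arm <- design$arm == a
    if (!any(design$perturbation_id[in_arm] == "control")) {
      problems <- c(problems, sprintf("screen arm '%s' has no control sample", a))
    }
  }

  if (length(problems)) {
    abort(paste0("Invalid count experiment:\n",
                 paste0("- ", problems, collapse = "\n")))
  }

  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         annotation = annotation[match(rownames(counts), annotation$probe_id), ],
         design = design[match(colnames(counts), design$sample_id), ]),
    class = "count_experiment"
  )
}

#' @export
print.count_experiment <- function(x, ...) {
  cls <- table(x$annotation$probe_class)
  cat(sprintf("<count_experiment> %d probes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  probe classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  arms:", paste(unique(x$design$arm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

read_table_checked <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a probe count matrix with its annotation and design tables
#'
#' Reads three delimited text files (TSV by default, CSV via `delim = ","`)
#' and assembles a validated [count_experiment()]. The counts file must have
#' probe ids in its first column and one column per sample; non-integer or
#' negative entries are reported with their row number.
#'
#' @param counts_path,annotation_path,design_path Paths to the counts matrix,
#'   probe annotation and sample design files.
#' @param delim Field delimiter; tab by default.
#' @return A `count_experiment`.
#' @seealso [write_count_matrix()] for the inverse operation.
#' @export
read_count_matrix <- function(counts_path, annotation_path, design_path,
                              delim = "\t") {
  raw <- read_table_checked(counts_path, delim)
  if (ncol(raw) < 2L) abort("Counts file needs a probe-id column plus >= 1 sample column.")
  probe_ids <- as.character(raw[[1L]])
  mat_df <- raw[, -1L, drop = FALSE]
  bad_rows <- which(!purrr::map_lgl(seq_len(nrow(mat_df)), function(i) {
    v <- as.numeric(unlist(mat_df[i, ]))
    all(is.finite(v)) && all(v >= 0) && all(v == round(v))
  }))
  if (length(bad_rows)) {
    abort(sprintf(
      "Non-integer or negative counts at data line(s): %s (probes %s)",
      id_list(as.character(bad_rows)), id_list(probe_ids[bad_rows])))
  }
  counts <- as.matrix(mat_df)
  storage.mode(counts) <- "integer"
  rownames(counts) <- probe_ids

  annotation <- read_table_checked(annotation_path, delim)
  design <- read_table_checked(design_path, delim)
  count_experiment(counts, annotation, design)
}

#' Write a count experiment to delimited text files
#'
#' Writes `counts.tsv`, `annotation.tsv` and `design.tsv` under `dir`
#' (extension follows `delim`). Round-trips bit-for-bit with
#' [read_count_matrix()].
#'
#' @param x A `count_experiment`.
#' @param dir Output directory, created if needed.
#' @param delim Field delimiter; tab by default.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_count_matrix <- function(x, dir, delim = "\t") {
  stopifnot(inherits(x, "count_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (identical(delim, ",")) "csv" else "tsv"
  paths <- c(counts = file.path(dir, paste0("counts.", ext)),
             annotation = file.path(dir, paste0("annotation.", ext)),
             design = file.path(dir, paste0("design.", ext)))
  cnt <- tibble::as_tibble(x$counts, rownames = "probe_id")
  readr::write_delim(cnt, paths[["counts"]], delim = delim)
  readr::write_delim(x$annotation, paths[["annotation"]], delim = delim)
  readr::write_delim(x$design, paths[["design"]], delim = delim)
  invisible(paths)
}

#' Gene signature
#'
#' An ordered set of unique gene identifiers with a name, as carried in GMT
#' gene-set files.
#'
#' @param name Signature name (GMT first field).
#' @param genes Character vector of gene ids; duplicates are collapsed with a
#'   warning, order of first occurrence is kept.
#' @param description Optional free-text description (GMT second field).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warn(sprintf("Signature '%s': duplicated gene ids collapsed: %s",
                 name, id_list(unique(genes[duplicated(genes)]))))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d genes\n", x$name, length(x$genes)))
  if (length(x$genes)) cat(" ", id_list(x$genes, 8L), "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then tab-separated gene ids.
#' Lines with fewer than three fields (or empty lines) are format errors
#' reported with their line number; duplicated genes within a line are
#' collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sigs <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (!nzchar(line) || length(fields) < 3L) {
      abort(sprintf("Malformed GMT line %d: need >= 3 tab-separated fields.", i))
    }
    gene_signature(fields[1L], fields[-(1:2)], description = fields[2L])
  })
  names(sigs) <- purrr::map_chr(sigs, "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A `gene_signature` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- purrr::map_chr(signatures, function(s) {
    stopifnot(inherits(s, "gene_signature"))
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
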