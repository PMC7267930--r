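# Readers/writers for every tabular artifact, with strict validation.
# Formats: TSV for time series, matrices and partitions; CSV for phenotype;
# JSON for configs and manifests. Matrices are serialized at 9 significant
# digits so outputs are diff-able and stable across runs.

MATRIX_DIGITS <- 9L

#' Canonical seven-network vocabulary
#'
#' Fixed ordering used everywhere a network axis appears: visual (VIS),
#' somatomotor (SMN), dorsal attention (DAN), ventral attention (VAN),
#' limbic (LIM), control (CON), default-mode (DMN).
#'
#' @return character vector of the 7 network codes.
#' @export
yeo7_networks <- function() {
  c("VIS", "SMN", "DAN", "VAN", "LIM", "CON", "DMN")
}

# 17-scheme: each 7-network split into subnetworks (2,2,2,2,2,3,4 -> 17),
# mirroring the usual refinement of the canonical parcellation.
yeo17_split <- function() {
  c(VIS = 2L, SMN = 2L, DAN = 2L, VAN = 2L, LIM = 2L, CON = 3L, DMN = 4L)
}

#' Construct a parcellated time-series object
#'
#' @param subject_id subject identifier.
#' @param data numeric time-by-node matrix, no missing values.
#' @param tr sampling interval in seconds.
#' @param node_ids unique node identifiers aligned to the columns of `data`.
#' @return an object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(subject_id, data, tr, node_ids = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(node_ids)) node_ids <- node_id_labels(ncol(data))
  if (!is.numeric(data) || nrow(data) < 2L || ncol(data) < 2L) {
    stop_dynmod("time series must be a numeric matrix with >= 2 time points and >= 2 nodes",
                class = "dynmod_parse_error")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop_dynmod(sprintf("non-finite value at row %d, column %d (%s)",
                        bad[1], bad[2], node_ids[bad[2]]),
                class = "dynmod_parse_error")
  }
  if (anyDuplicated(node_ids) || length(node_ids) != ncol(data)) {
    stop_dynmod("node_ids must be unique and match the number of columns",
                class = "dynmod_parse_error")
  }
  if (!is_number(tr) || tr <= 0) {
    stop_dynmod("tr must be a positive number of seconds", class = "dynmod_parse_error")
  }
  colnames(data) <- node_ids
  structure(
    list(subject_id = as.character(subject_id), data = data, tr = tr,
         node_ids = as.character(node_ids)),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts '%s': %d time points x %d nodes, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Read a parcellated time series from TSV
#'
#' Expects a header row of node ids and one row per time point. The TR is
#' not stored in the file and is supplied by the caller.
#'
#' @param path TSV file path.
#' @param tr sampling interval in seconds.
#' @param subject_id subject id; defaults to the file name without extension.
#' @return a `parcellated_ts`.
#' @export
read_timeseries <- function(path, tr = 0.645, subject_id = NULL) {
  if (!file.exists(path)) stop_dynmod(paste("no such file:", path), class = "dynmod_parse_error")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "numeric"),
    error = function(e) stop_dynmod(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                                    class = "dynmod_parse_error")
  )
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  parcellated_ts(subject_id, as.matrix(df), tr = tr, node_ids = colnames(df))
}

#' Write a parcellated time series to TSV
#'
#' @param series a `parcellated_ts`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "parcellated_ts"))
  m <- series$data
  df <- as.data.frame(signif(m, MATRIX_DIGITS))
  names(df) <- series$node_ids
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the canonical node labeling for a 114-node parcellation
#'
#' Synthetic stand-in for the atlas lookup table: nodes are split into left
#' and right hemispheres, each hemisphere into the 7 canonical networks, and
#' each network into its 17-scheme subnetworks. Real analyses should load
#' the atlas table with [read_node_labeling()]; this constructor exists so
#' the synthetic pipeline is self-contained.
#'
#' @param n_nodes number of nodes; must be even (hemisphere split).
#' @return data.frame with columns `node_id`, `network_7`, `network_17`,
#'   `hemisphere`.
#' @export
make_node_labeling <- function(n_nodes = 114L) {
  if (!is_count(n_nodes, 2) || n_nodes %% 2L != 0L) {
    stop_dynmod("n_nodes must be a positive even integer", class = "dynmod_parse_error")
  }
  half <- n_nodes %/% 2L
  one_hemi <- function(hemi) {
    net7 <- yeo7_networks()[as.integer(cut(seq_len(half), 7L, labels = FALSE))]
    split17 <- yeo17_split()
    net17 <- unlist(lapply(yeo7_networks(), function(nw) {
      idx <- which(net7 == nw)
      k <- split17[[nw]]
      paste0(nw, as.integer(cut(seq_along(idx), k, labels = FALSE)))
    }), use.names = FALSE)
    data.frame(network_7 = net7, network_17 = net17, hemisphere = hemi,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_hemi("LH"), one_hemi("RH"))
  out <- cbind(node_id = node_id_labels(n_nodes), out)
  validate_node_labeling(out)
}

validate_node_labeling <- function(df) {
  need <- c("node_id", "network_7", "network_17", "hemisphere")
  if (!all(need %in% names(df))) {
    stop_dynmod(paste("labeling must have columns:", paste(need, collapse = ", ")),
                class = "dynmod_parse_error")
  }
  if (anyDuplicated(df$node_id)) {
    stop_dynmod("duplicate node ids in labeling", class = "dynmod_parse_error")
  }
  if (!all(df$network_7 %in% yeo7_networks())) {
    stop_dynmod("network_7 labels outside the declared 7-network vocabulary",
                class = "dynmod_parse_error")
  }
  if (!all(df$hemisphere %in% c("LH", "RH"))) {
    stop_dynmod("hemisphere must be LH or RH", class = "dynmod_parse_error")
  }
  if (anyNA(df$network_17) || any(df$network_17 == "")) {
    stop_dynmod("every node needs a 17-scheme label", class = "dynmod_parse_error")
  }
  df[need]
}

#' Read a node labeling table (TSV)
#' @param path TSV with columns node_id, network_7, network_17, hemisphere.
#' @return validated labeling data.frame.
#' @export
read_node_labeling <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_node_labeling(df)
}

#' Write a node labeling table (TSV)
#' @param labeling labeling data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_labeling <- function(labeling, path) {
  labeling <- validate_node_labeling(labeling)
  write.table(labeling, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table (CSV)
#'
#' Required columns: `subject_id`, `fsiq`, `age`, `sex`, `handedness`,
#' `mean_fd`. Sex and handedness are 0/1 numeric codes (they enter the
#' models as numeric covariates).
#'
#' @param path CSV path. Lines starting with `#` are ignored.
#' @return validated phenotype data.frame.
#' @export
read_phenotype <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_phenotype(df)
}

validate_phenotype <- function(df) {
  need <- c("subject_id", "fsiq", "age", "sex", "handedness", "mean_fd")
  if (!all(need %in% names(df))) {
    stop_dynmod(paste("phenotype must have columns:", paste(need, collapse = ", ")),
                class = "dynmod_parse_error")
  }
  if (anyDuplicated(df$subject_id)) {
    stop_dynmod("duplicate subject ids in phenotype table", class = "dynmod_parse_error")
  }
  num <- need[-1]
  if (anyNA(df[num])) {
    stop_dynmod("missing covariate or phenotype values", class = "dynmod_parse_error")
  }
  df[need]
}

#' Write a phenotype table (CSV)
#' @param phenotype phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  phenotype <- validate_phenotype(phenotype)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sex: 0 = female, 1 = male; handedness: 0 = left, 1 = right; mean_fd in mm", con)
  write.table(phenotype, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix to TSV (9 significant digits)
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) rownames(m) <- node_id_labels(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- node_id_labels(ncol(m))
  df <- data.frame(node_id = rownames(m), signif(m, MATRIX_DIGITS),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix from TSV written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a partition to TSV (node_id, module_id)
#' @param partition a `dynmod_partition` (see [louvain_once()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "dynmod_partition"))
  df <- data.frame(node_id = names(partition$assignment),
                   module_id = as.integer(partition$assignment))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition from TSV (node_id, module_id)
#'
#' Restores a partition written by [write_partition()]. The quality value is
#' recomputed against `matrix` when one is supplied; otherwise `q` is `NA`.
#'
#' @param path TSV path.
#' @param matrix optional connectivity matrix to recompute `q` on.
#' @param gamma resolution to attach (and to use for the recomputation).
#' @param variant quality-function variant for the recomputation.
#' @return a `dynmod_partition`.
#' @export
read_partition <- function(path, matrix = NULL, gamma = 1, variant = "signed") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("node_id", "module_id") %in% names(df))) {
    stop_dynmod("partition file needs node_id and module_id columns",
                class = "dynmod_parse_error")
  }
  q <- if (!is.null(matrix)) {
    modularity_q(matrix, df$module_id, gamma = gamma, variant = variant)
  } else {
    NA_real_
  }
  assignment <- as.integer(df$module_id)
  names(assignment) <- df$node_id
  structure(
    list(assignment = assignment, gamma = gamma, q = q,
         n_modules = length(unique(assignment)), run_seed = NA_integer_,
         variant = variant),
    class = "dynmod_partition"
  )
}

#' Align a cohort of time series with labeling and phenotype
#'
#' Checks that every subject shares the labeling's node ids in identical
#' order and that the phenotype covers every subject. Extra phenotype rows
#' are dropped with a warning; a missing subject or a node-order mismatch is
#' an error naming the subject.
#'
#' @param series list of `parcellated_ts`.
#' @param labeling node labeling data.frame.
#' @param phenotype phenotype data.frame, or `NULL` to skip that check.
#' @return list of class `dynmod_cohort` with `series`, `labeling`,
#'   `phenotype` (reordered to subject order).
#' @export
align_cohort <- function(series, labeling, phenotype = NULL) {
  if (length(series) == 0L) {
    stop_dynmod("empty cohort", class = "dynmod_alignment_error")
  }
  labeling <- validate_node_labeling(labeling)
  ref <- labeling$node_id
  for (s in series) {
    if (!inherits(s, "parcellated_ts")) {
      stop_dynmod("all cohort members must be parcellated_ts objects",
                  class = "dynmod_alignment_error")
    }
    if (!identical(s$node_ids, ref)) {
      stop_dynmod(sprintf("subject '%s': node ids/order do not match the labeling",
                          s$subject_id),
                  class = "dynmod_alignment_error")
    }
  }
  ids <- vapply(series, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    stop_dynmod("duplicate subject ids in cohort", class = "dynmod_alignment_error")
  }
  if (!is.null(phenotype)) {
    phenotype <- validate_phenotype(phenotype)
    missing <- setdiff(ids, phenotype$subject_id)
    if (length(missing) > 0) {
      stop_dynmod(paste("phenotype missing for subjects:", paste(missing, collapse = ", ")),
                  class = "dynmod_alignment_error")
    }
    extra <- setdiff(phenotype$subject_id, ids)
    if (length(extra) > 0) {
      warning(sprintf("dropping %d phenotype rows without time series: %s",
                      length(extra), paste(head(extra, 5), collapse = ", ")))
    }
    phenotype <- phenotype[match(ids, phenotype$subject_id), , drop = FALSE]
    rownames(phenotype) <- NULL
  }
  structure(list(series = series, labeling = labeling, phenotype = phenotype),
            class = "dynmod_cohort")
}
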