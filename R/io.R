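#' Read a spot-by-gene count matrix
#'
#' Accepts either MatrixMarket triplet format (`counts` ending in `.mtx`,
#' with companion `genes`/`barcodes` files listing ids, one per line, first
#' column used) or a dense CSV whose header row names the genes and whose
#' first column holds spot ids. Entries must be non-negative integers; file
#' order of genes and spots is preserved.
#'
#' @param counts Path to `.mtx` or `.csv`.
#' @param genes,barcodes Paths to id lists (required for `.mtx`).
#' @return A dense numeric matrix with spot ids as rownames and gene ids as
#'   colnames.
#' @export
read_counts <- function(counts, genes = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", counts)) {
    if (is.null(genes) || is.null(barcodes)) {
      abort("MatrixMarket input needs genes and barcodes files",
            class = "spanr_format_error")
    }
    m <- as.matrix(Matrix::readMM(counts))
    gene_ids <- readr::read_tsv(genes, col_names = FALSE, show_col_types = FALSE)[[1]]
    spot_ids <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)[[1]]
    # genes-by-spots on disk (convention of expression MTX bundles)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(spot_ids)) {
      abort(sprintf("matrix is %d x %d but got %d genes and %d barcodes",
                    nrow(m), ncol(m), length(gene_ids), length(spot_ids)),
            class = "spanr_format_error")
    }
    Y <- t(m)
    dimnames(Y) <- list(spot_ids, gene_ids)
  } else {
    df <- readr::read_csv(counts, show_col_types = FALSE)
    Y <- as.matrix(df[, -1, drop = FALSE])
    rownames(Y) <- as.character(df[[1]])
  }
  if (any(is.na(Y)) || any(Y < 0) || any(Y != round(Y))) {
    bad <- which(is.na(Y) | Y < 0 | Y != round(Y), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer or negative count at spot %s, gene %s",
                  rownames(Y)[bad[1]], colnames(Y)[bad[2]]),
          class = "spanr_format_error")
  }
  storage.mode(Y) <- "double"
  Y
}

#' Read a marker table into an indicator matrix
#'
#' The table has one row per (gene, type) pair, columns `gene` and
#' `cell_type` (CSV or TSV, by extension, or an in-memory data frame).
#' The indicator is built over the intersection with `gene_ids`: unknown
#' genes are dropped with a warning, duplicated pairs deduplicated with a
#' warning, and an empty intersection is fatal. Type order is
#' first-appearance order; a gene may mark several types.
#'
#' @param markers Path or data frame with columns `gene`, `cell_type`.
#' @param gene_ids Gene ids available in the count matrix.
#' @return Binary indicator matrix (marker genes x types).
#' @export
read_markers <- function(markers, gene_ids) {
  if (is.character(markers)) {
    reader <- if (grepl("\\.tsv$", markers)) readr::read_tsv else readr::read_csv
    markers <- reader(markers, show_col_types = FALSE)
  }
  markers <- tibble::as_tibble(markers)
  if (!all(c("gene", "cell_type") %in% names(markers))) {
    abort("marker table needs columns gene and cell_type",
          class = "spanr_format_error")
  }
  if (anyDuplicated(markers[c("gene", "cell_type")])) {
    warn("duplicate (gene, cell_type) rows in the marker table; deduplicated")
    markers <- dplyr::distinct(markers, .data$gene, .data$cell_type)
  }
  unknown <- setdiff(unique(markers$gene), gene_ids)
  if (length(unknown)) {
    warn(paste0("marker gene(s) absent from the count matrix, skipped: ",
                paste(head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) sprintf(" (+%d more)", length(unknown) - 5) else ""))
    markers <- markers[markers$gene %in% gene_ids, , drop = FALSE]
  }
  if (nrow(markers) == 0) {
    abort("no marker gene overlaps the count matrix", class = "spanr_format_error")
  }
  types <- unique(markers$cell_type)
  genes <- unique(markers$gene)
  rho <- matrix(0, length(genes), length(types), dimnames = list(genes, types))
  rho[cbind(match(markers$gene, genes), match(markers$cell_type, types))] <- 1
  rho
}

#' Read spot coordinates
#'
#' CSV with header: either `spot_id,row,col` (array platforms) or
#' `spot_id,x,y` (imaging platforms).
#'
#' @param path Coordinates CSV.
#' @return A tibble; its columns determine the platform mode.
#' @export
read_coords <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!("spot_id" %in% names(df)) ||
      !(all(c("row", "col") %in% names(df)) || all(c("x", "y") %in% names(df)))) {
    abort("coordinates need columns spot_id + (row, col) or (x, y)",
          class = "spanr_format_error")
  }
  df
}

#' Read a covariate table
#'
#' CSV `spot_id,<name>...`. Columns named in `categorical` (e.g. batch ids)
#' are one-hot encoded with the first level as reference; the rest are used
#' as numeric covariates as given.
#'
#' @param path Covariates CSV.
#' @param categorical Character vector of column names to one-hot encode.
#' @return Numeric covariate matrix with spot ids as rownames.
#' @export
read_covariates <- function(path, categorical = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  parts <- lapply(names(df), function(nm) {
    if (nm %in% categorical) {
      f <- factor(df[[nm]])
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    } else {
      matrix(as.numeric(df[[nm]]), ncol = 1, dimnames = list(NULL, nm))
    }
  })
  X <- do.call(cbind, parts)
  rownames(X) <- ids
  X
}

#' Run the full assignment pipeline from a configuration
#'
#' Validates the configuration, reads counts / markers / coordinates (and
#' optional covariates), builds the platform-appropriate neighbour graph
#' (`visium` = hex grid, `st` = square grid, `knn` = k-nearest Euclidean
#' neighbours), restricts the counts to the marker panel, fits the model and
#' writes a results bundle to `out_dir`: `labels.csv`, `posterior.csv`,
#' `params.json` (parameters, config echo, per-iteration history) and
#' `run.log`.
#'
#' @param config A list (or path to a YAML file) with elements `counts`,
#'   `markers`, `coords` (paths; plus `genes`/`barcodes` for MTX and
#'   optionally `covariates` and `categorical_covariates`), `platform`
#'   (`"visium"`, `"st"` or `"knn"`), `k` (for `knn`), `out_dir`, and any
#'   [span_config()] fields.
#' @return The fitted `span_fit`, invisibly.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("counts", "markers", "coords", "platform", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("config is missing field(s): ", paste(missing, collapse = ", ")),
          class = "spanr_invalid_config")
  }
  for (f in intersect(c("counts", "genes", "barcodes", "markers", "coords",
                        "covariates"), names(config))) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("file for '%s' not found: %s", f, config[[f]]),
            class = "spanr_invalid_config")
    }
  }
  platform <- match.arg(config$platform, c("visium", "st", "knn"))

  Y <- read_counts(config$counts, config$genes, config$barcodes)
  rho <- read_markers(config$markers, colnames(Y))
  Y <- Y[, rownames(rho), drop = FALSE] # the model sees marker genes only
  coords <- read_coords(config$coords)
  coords <- coords[match(rownames(Y), coords$spot_id), , drop = FALSE]
  if (anyNA(coords$spot_id)) {
    abort("coordinates missing for some spots in the count matrix",
          class = "spanr_invalid_config")
  }
  graph <- switch(platform,
    visium = build_grid_graph(coords, "hex"),
    st = build_grid_graph(coords, "square"),
    knn = build_knn_graph(coords, k = config$k %||% 15))
  X <- if (!is.null(config$covariates)) {
    read_covariates(config$covariates,
                    categorical = config$categorical_covariates %||% character())
  } else NULL
  if (!is.null(X)) X <- X[rownames(Y), , drop = FALSE]

  cfg_fields <- intersect(names(config), names(formals(span_config)))
  span_cfg <- do.call(span_config, config[cfg_fields])
  fit <- fit_span(Y, rho, graph, X, config = span_cfg)
  write_results(fit, config$out_dir, config_echo = config)
  invisible(fit)
}

#' Write a results bundle
#'
#' @param fit A `span_fit`.
#' @param out_dir Output directory (created if needed).
#' @param config_echo Optional configuration list echoed into `params.json`.
#' @export
write_results <- function(fit, out_dir, config_echo = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble::tibble(spot_id = fit$spot_ids, assigned_type = fit$type),
    file.path(out_dir, "labels.csv"))
  post <- tibble::as_tibble(as.data.frame(fit$posterior))
  names(post) <- fit$type_names
  readr::write_csv(dplyr::bind_cols(tibble::tibble(spot_id = fit$spot_ids), post),
                   file.path(out_dir, "posterior.csv"))
  params <- list(
    mixture = list(delta = unname(exp(fit$mixture_params$delta_raw)),
                   beta0 = unname(fit$mixture_params$beta0),
                   beta = unname(fit$mixture_params$beta),
                   a = unname(softplus(fit$mixture_params$a_raw)),
                   b = unname(softplus(fit$mixture_params$b_raw)),
                   centers = fit$mixture_params$centers,
                   pi = mixture_pi(fit$mixture_params)),
    hmrf = list(eta = fit$hmrf_params$eta, zeta = hmrf_zeta(fit$hmrf_params)),
    type_names = fit$type_names,
    converged = fit$converged,
    history = fit$history,
    config = fit$config,
    config_echo = config_echo)
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  log_lines <- c(
    sprintf("spanr fit: %d spots, K = %d", length(fit$z), length(fit$type_names)),
    sprintf("iter %d: label change %.4f%%, conditional loglik %.3f, pseudolikelihood %s",
            fit$history$iter, 100 * fit$history$changed_fraction,
            fit$history$conditional_loglik,
            ifelse(is.na(fit$history$pseudolikelihood), "NA",
                   sprintf("%.3f", fit$history$pseudolikelihood))),
    sprintf("converged: %s", fit$converged))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(file.path(out_dir, c("labels.csv", "posterior.csv", "params.json", "run.log")))
}

#' Write a simulated dataset as a portable bundle
#'
#' Writes `counts.mtx` + `genes.tsv` + `barcodes.tsv` (genes-by-spots
#' MatrixMarket), `coords.csv`, `markers.csv` (gene, cell_type pairs),
#' `truth.csv`, `batches.csv` (when present) and the resolved configuration
#' as `sim_config.yaml`.
#'
#' @param dataset A `span_sim`.
#' @param out_dir Output directory (created if needed).
#' @export
write_sim_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(dataset$Y), sparse = TRUE)
  Matrix::writeMM(m, file.path(out_dir, "counts.mtx"))
  writeLines(colnames(dataset$Y), file.path(out_dir, "genes.tsv"))
  writeLines(rownames(dataset$Y), file.path(out_dir, "barcodes.tsv"))
  readr::write_csv(dataset$coords, file.path(out_dir, "coords.csv"))
  idx <- which(dataset$rho == 1, arr.ind = TRUE)
  readr::write_csv(
    tibble::tibble(gene = rownames(dataset$rho)[idx[, 1]],
                   cell_type = colnames(dataset$rho)[idx[, 2]]),
    file.path(out_dir, "markers.csv"))
  readr::write_csv(
    tibble::tibble(spot_id = dataset$coords$spot_id,
                   true_type = type_labels(dataset$config$K)[dataset$z_true]),
    file.path(out_dir, "truth.csv"))
  if (!is.null(dataset$batch_ids)) {
    readr::write_csv(
      tibble::tibble(spot_id = dataset$coords$spot_id, batch = dataset$batch_ids),
      file.path(out_dir, "batches.csv"))
  }
  yaml::write_yaml(dataset$config, file.path(out_dir, "sim_config.yaml"))
  invisible(out_dir)
}
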