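#' Synthetic SRT simulation design
#'
#' A Splatter-style generative recipe for group-structured spatial count
#' data: gene base means are Gamma-distributed, each group up-regulates a
#' `de_prob` fraction of genes by log-normal differential-expression (DE)
#' factors `exp(N(0, sigma^2))`, spot library sizes are log-normal, expected
#' counts are the library size times the group's normalised expression
#' profile, and counts are negative binomial. Genes whose DE factor exceeds
#' `marker_threshold` in a group become that group's markers. Types are laid
#' out as contiguous horizontal bands on a square grid, emulating layered
#' cortical tissue.
#'
#' `sigma` is the main difficulty dial: larger values give stronger
#' between-group log fold changes, hence stronger signal.
#'
#' Defaults reproduce the reference simulation design this generator
#' emulates: 3611 spots from 7 groups over 2500 genes at `sigma = 0.3`,
#' with near-equal layered bands standing in for cortical-layer sizes.
#'
#' @param n_spots,n_genes,K Problem dimensions.
#' @param sigma Log-scale SD of the DE factors.
#' @param de_prob Fraction of genes DE per group (default 0.1).
#' @param marker_threshold DE factor above which a gene is a marker
#'   (default 1.5, strict inequality).
#' @param base_shape,base_rate Gamma parameters of gene base means.
#' @param lib_loc,lib_scale Log-normal library-size parameters.
#' @param nb_size_sim NB inverse-dispersion used when drawing counts.
#' @param group_sizes Spots per type (default: as equal as possible,
#'   summing to `n_spots`).
#' @param spatial_noise_ratio Fraction of spots whose expression and label
#'   are swapped in cross-group pairs (see [inject_spatial_noise()]).
#' @param fake_marker_ratio,misassign_ratio Marker corruption levels (see
#'   [corrupt_markers()]).
#' @param n_batches,batch_sigma Batch structure (see [add_batch_effects()]).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config.
#' @export
sim_config <- function(n_spots = 3611L, n_genes = 2500L, K = 7L,
                       sigma = 0.3, de_prob = 0.1, marker_threshold = 1.5,
                       base_shape = 0.6, base_rate = 0.3,
                       lib_loc = log(2000), lib_scale = 0.35,
                       nb_size_sim = 2,
                       group_sizes = NULL,
                       spatial_noise_ratio = 0, fake_marker_ratio = 0,
                       misassign_ratio = 0,
                       n_batches = 1L, batch_sigma = 0,
                       seed = 1L) {
  stopifnot(sigma >= 0, de_prob > 0, de_prob <= 1, marker_threshold > 1,
            spatial_noise_ratio >= 0, spatial_noise_ratio <= 1,
            fake_marker_ratio >= 0, fake_marker_ratio <= 1,
            misassign_ratio >= 0, misassign_ratio <= 1, n_batches >= 1)
  if (is.null(group_sizes)) {
    group_sizes <- rep(n_spots %/% K, K)
    extra <- n_spots - sum(group_sizes)
    if (extra > 0) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
  }
  stopifnot(sum(group_sizes) == n_spots, length(group_sizes) == K)
  list(n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
       K = as.integer(K), sigma = sigma, de_prob = de_prob,
       marker_threshold = marker_threshold,
       base_shape = base_shape, base_rate = base_rate,
       lib_loc = lib_loc, lib_scale = lib_scale, nb_size_sim = nb_size_sim,
       group_sizes = as.integer(group_sizes),
       spatial_noise_ratio = spatial_noise_ratio,
       fake_marker_ratio = fake_marker_ratio,
       misassign_ratio = misassign_ratio,
       n_batches = as.integer(n_batches), batch_sigma = batch_sigma,
       seed = as.integer(seed))
}

#' Banded spatial layout
#'
#' Places `n_spots` on the smallest near-square grid that holds them and
#' assigns types `1..K` as contiguous horizontal bands whose sizes are
#' `group_sizes`, mimicking layered tissue (row-major fill, top band first).
#'
#' @param config A [sim_config()].
#' @return List with `coords` (tibble `spot_id`, `row`, `col`) and `z_true`.
#' @export
make_layout <- function(config) {
  n <- config$n_spots
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  if (nrow_grid * ncol_grid < n) {
    abort("grid too small for the requested number of spots",
          class = "spanr_invalid_layout")
  }
  idx <- seq_len(n) - 1L
  coords <- tibble::tibble(
    spot_id = sprintf("spot%04d", seq_len(n)),
    row = idx %/% ncol_grid + 1L,
    col = idx %% ncol_grid + 1L)
  z_true <- rep.int(seq_len(config$K), config$group_sizes)
  list(coords = coords, z_true = z_true)
}

#' Simulate a spatial count dataset
#'
#' Draws a full synthetic dataset under a [sim_config()]: counts, true
#' labels, coordinates, DE factors and the derived marker panel. Corruption
#' steps requested in the config (`fake_marker_ratio`, `misassign_ratio`,
#' `spatial_noise_ratio`, batches) are applied in that order after the clean
#' draw.
#'
#' @param config A [sim_config()].
#' @return An object of class `span_sim`: list with `Y` (N-by-G counts over
#'   all simulated genes), `z_true`, `coords`, `rho` (marker-panel indicator,
#'   rows = marker genes only), `de_factors` (G-by-K), `base_means`,
#'   `lib_sizes`, `batch_ids` (or NULL), and the resolved `config`.
#'   Use [marker_view()] to extract the model's input (marker-gene counts and
#'   indicator).
#' @export
simulate_dataset <- function(config = sim_config()) {
  G <- config$n_genes; K <- config$K; N <- config$n_spots
  n_de <- round(config$de_prob * G)
  if (n_de < 1 || config$de_prob * G < K) {
    abort("de_prob * n_genes too small to yield markers for every group",
          class = "spanr_too_few_markers")
  }
  layout <- make_layout(config)

  dataset <- with_local_seed(derive_seed(config$seed, "sim"), {
    gene_ids <- sprintf("gene%05d", seq_len(G))
    base_means <- rgamma(G, shape = config$base_shape, rate = config$base_rate)
    de_factors <- matrix(1, G, K, dimnames = list(gene_ids, type_labels(K)))
    for (k in seq_len(K)) {
      de_idx <- sample.int(G, n_de)
      de_factors[de_idx, k] <- exp(rnorm(n_de, 0, config$sigma))
    }
    lib_sizes <- rlnorm(N, config$lib_loc, config$lib_scale)
    Y <- draw_counts(base_means, de_factors, lib_sizes, layout$z_true,
                     config$nb_size_sim)
    rownames(Y) <- layout$coords$spot_id
    colnames(Y) <- gene_ids
    list(Y = Y, base_means = setNames(base_means, gene_ids),
         de_factors = de_factors, lib_sizes = lib_sizes)
  })

  rho <- select_markers(dataset$de_factors, config$marker_threshold)
  out <- structure(
    list(Y = dataset$Y, z_true = layout$z_true, coords = layout$coords,
         rho = rho, de_factors = dataset$de_factors,
         base_means = dataset$base_means, lib_sizes = dataset$lib_sizes,
         batch_ids = NULL, config = config),
    class = "span_sim")

  if (config$fake_marker_ratio > 0) {
    out$rho <- corrupt_markers(out$rho, out$de_factors, mode = "fake",
                               ratio = config$fake_marker_ratio,
                               seed = derive_seed(config$seed, "corrupt"))
  }
  if (config$misassign_ratio > 0) {
    out$rho <- corrupt_markers(out$rho, out$de_factors, mode = "misassign",
                               ratio = config$misassign_ratio,
                               seed = derive_seed(config$seed, "corrupt") + 1L)
  }
  if (config$spatial_noise_ratio > 0) {
    out <- inject_spatial_noise(out, config$spatial_noise_ratio,
                                seed = derive_seed(config$seed, "noise"))
  }
  if (config$n_batches > 1L) {
    out <- add_batch_effects(out, config$n_batches, config$batch_sigma,
                             seed = derive_seed(config$seed, "batch"))
  }
  out
}

draw_counts <- function(base_means, de_factors, lib_sizes, z, nb_size) {
  group_means <- base_means * de_factors            # G x K
  props <- sweep(group_means, 2L, colSums(group_means), `/`)
  mu <- lib_sizes * t(props[, z, drop = FALSE])     # N x G (recycles by spot)
  Y <- matrix(rnbinom(length(mu), size = nb_size, mu = mu), nrow(mu), ncol(mu))
  storage.mode(Y) <- "double"
  Y
}

type_labels <- function(K) paste0("type", seq_len(K))

#' Derive the marker panel from DE factors
#'
#' A gene is a marker for a group when its DE factor strictly exceeds the
#' threshold there. Genes marking no group are dropped from the panel (the
#' model only sees marker genes). Groups left without any marker trigger a
#' warning naming them.
#'
#' @param de_factors G-by-K matrix of DE factors (rownames = gene ids).
#' @param threshold Selection threshold (default 1.5, strict).
#' @return Binary marker indicator over the selected genes only.
#' @export
select_markers <- function(de_factors, threshold = 1.5) {
  stopifnot(all(de_factors >= 0))
  rho <- (de_factors > threshold) * 1
  empty_groups <- colSums(rho) == 0
  if (any(empty_groups)) {
    warn(paste0("no marker gene for group(s): ",
                paste(colnames(de_factors)[empty_groups], collapse = ", ")),
         class = "spanr_missing_markers")
  }
  rho[rowSums(rho) > 0, , drop = FALSE]
}

#' Restrict a simulated dataset to its marker panel
#'
#' @param dataset A `span_sim`.
#' @return List with `Y` (counts over panel genes) and `rho`, aligned.
#' @export
marker_view <- function(dataset) {
  genes <- rownames(dataset$rho)
  list(Y = dataset$Y[, genes, drop = FALSE], rho = dataset$rho)
}

#' Inject spatial noise by cross-group spot swaps
#'
#' Samples `floor(ratio * N / 2)` disjoint pairs of spots carrying different
#' labels and swaps each pair's count rows and labels, leaving coordinates
#' untouched: expression and type move, position does not, so the label map
#' gets rougher while the marginal composition is conserved.
#'
#' @param dataset A `span_sim`.
#' @param ratio Fraction of spots involved (in `[0, 1]`).
#' @param seed Integer seed.
#' @export
inject_spatial_noise <- function(dataset, ratio, seed = 1L) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (ratio == 0) return(dataset)
  K <- dataset$config$K
  if (K < 2L) {
    warn("spatial noise needs at least two groups; returning dataset unchanged")
    return(dataset)
  }
  n_pairs <- floor(ratio * nrow(dataset$Y) / 2)
  if (n_pairs == 0) return(dataset)
  with_local_seed(seed, {
    pool <- sample.int(nrow(dataset$Y))
    z <- dataset$z_true
    made <- 0L
    while (made < n_pairs && length(pool) >= 2L) {
      i <- pool[1L]
      partners <- pool[-1L][z[pool[-1L]] != z[i]]
      if (!length(partners)) { pool <- pool[-1L]; next }
      j <- partners[sample.int(length(partners), 1L)]
      tmp <- dataset$Y[i, ]; dataset$Y[i, ] <- dataset$Y[j, ]; dataset$Y[j, ] <- tmp
      zt <- z[i]; z[i] <- z[j]; z[j] <- zt
      pool <- setdiff(pool, c(i, j))
      made <- made + 1L
    }
    if (made < n_pairs) {
      warn(sprintf("only %d of %d cross-group pairs could be formed", made, n_pairs))
    }
    dataset$z_true <- z
    dataset
  })
}

#' Corrupt the marker panel
#'
#' Emulates imperfect prior knowledge. `mode = "fake"` replaces
#' `floor(ratio * n_markers)` marker genes with uniformly chosen non-DE
#' genes, each assigned one uniformly random type (panel size preserved).
#' `mode = "misassign"` moves the same number of marker genes to a uniformly
#' chosen wrong type (each corrupted gene then marks exactly one type).
#'
#' @param rho Marker-panel indicator (rows = marker genes, rownames = ids).
#' @param de_factors Full G-by-K DE factor matrix (rownames = all gene ids).
#' @param mode `"fake"` or `"misassign"`.
#' @param ratio Fraction of marker genes corrupted (in `[0, 1]`).
#' @param seed Integer seed.
#' @return A corrupted marker-panel indicator.
#' @export
corrupt_markers <- function(rho, de_factors, mode = c("fake", "misassign"),
                            ratio, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(ratio >= 0, ratio <= 1)
  if (ratio == 0) return(rho)
  K <- ncol(rho)
  n_markers <- nrow(rho)
  n_cor <- floor(ratio * n_markers)
  if (n_cor == 0) return(rho)
  with_local_seed(seed, {
    victims <- sample.int(n_markers, n_cor)
    if (mode == "fake") {
      non_de <- setdiff(rownames(de_factors)[rowSums(de_factors != 1) == 0],
                        rownames(rho))
      if (length(non_de) < n_cor) {
        abort("not enough non-DE genes to draw fake markers from",
              class = "spanr_invalid_ratio")
      }
      fakes <- sample(non_de, n_cor)
      new_rows <- matrix(0, n_cor, K, dimnames = list(fakes, colnames(rho)))
      new_rows[cbind(seq_len(n_cor), sample.int(K, n_cor, replace = TRUE))] <- 1
      rho <- rbind(rho[-victims, , drop = FALSE], new_rows)
    } else {
      for (g in victims) {
        wrong <- which(rho[g, ] == 0)
        if (!length(wrong)) next # gene marks every type; nothing wrong to move to
        pick <- wrong[sample.int(length(wrong), 1L)]
        rho[g, ] <- 0
        rho[g, pick] <- 1
      }
    }
    rho
  })
}

#' Add multiplicative batch effects
#'
#' Partitions spots into `n_batches` contiguous index blocks, draws a
#' per-batch per-gene factor `exp(N(0, batch_sigma^2))`, scales the expected
#' counts and redraws all counts. Batch identity is recorded and can be
#' passed to the model as one-hot covariates via [batch_covariates()].
#'
#' @param dataset A `span_sim`.
#' @param n_batches Number of batches (>= 2).
#' @param batch_sigma Log-scale SD of the batch factors.
#' @param seed Integer seed.
#' @export
add_batch_effects <- function(dataset, n_batches, batch_sigma, seed = 1L) {
  stopifnot(n_batches >= 2)
  N <- nrow(dataset$Y); G <- ncol(dataset$Y)
  batch_ids <- as.integer(cut(seq_len(N), n_batches, labels = FALSE))
  with_local_seed(seed, {
    factors <- matrix(exp(rnorm(G * n_batches, 0, batch_sigma)), G, n_batches)
    group_means <- dataset$base_means * dataset$de_factors
    props <- sweep(group_means, 2L, colSums(group_means), `/`)
    mu <- dataset$lib_sizes * t(props[, dataset$z_true, drop = FALSE])
    mu <- mu * t(factors[, batch_ids, drop = FALSE])
    Y <- matrix(rnbinom(length(mu), size = dataset$config$nb_size_sim, mu = mu),
                N, G, dimnames = dimnames(dataset$Y))
    storage.mode(Y) <- "double"
    dataset$Y <- Y
    dataset$batch_ids <- batch_ids
    dataset$batch_factors <- factors
    dataset
  })
}

#' One-hot batch covariates (reference level dropped)
#'
#' @param dataset A `span_sim` with batch effects.
#' @return N-by-(n_batches - 1) indicator matrix, or a zero-column matrix if
#'   the dataset has no batches.
#' @export
batch_covariates <- function(dataset) {
  if (is.null(dataset$batch_ids)) return(matrix(0, nrow(dataset$Y), 0))
  b <- factor(dataset$batch_ids)
  stats::model.matrix(~b)[, -1, drop = FALSE]
}

#' @export
print.span_sim <- function(x, ...) {
  cat(sprintf("<span_sim> %d spots x %d genes, K = %d, sigma = %g; %d marker genes\n",
              nrow(x$Y), ncol(x$Y), x$config$K, x$config$sigma, nrow(x$rho)))
  invisible(x)
}
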