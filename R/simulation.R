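# Synthetic tumor cohorts: exposures x signatures with Poisson counts,
# emulating the published benchmark designs (presets sim1-sim6).

.rdirichlet <- function(n, concentration) {
  k <- length(concentration)
  g <- matrix(stats::rgamma(n * k, shape = concentration), n, k, byrow = TRUE)
  g / rowSums(g)
}

#' The packaged synthetic signature catalog
#'
#' Twelve synthetic 96-category signature profiles used by the
#' simulation presets when no external catalog is supplied: five dense
#' profiles (`SYN-D1..D5`, where more than 75% of categories contribute)
#' and seven sparse profiles (`SYN-S1..S7`, fewer than 50% contribute).
#' The sparse profiles are patterned on well-known mutational processes
#' (CpG deamination, C>A-dominated oxidative damage, APOBEC-like TpC
#' spikes, ...) but are constructed, not transcribed from any published
#' catalog.
#'
#' @return 12 x 96 matrix, rows summing to 1.
#' @export
synthetic_catalog <- function() {
  path <- system.file("extdata", "catalog_synthetic.tsv",
                      package = "sparsesigs", mustWork = TRUE)
  read_signature_matrix(path)
}

# fraction of categories contributing to a signature; the contribution
# threshold defaults to 1% of the uniform rate (1/960)
.contribution_fraction <- function(beta, threshold = 1 / 960) {
  rowMeans(beta > threshold)
}

#' Specify a synthetic cohort
#'
#' Bundles everything needed to generate one dataset: the generating
#' signatures (with one row designated as background), how often each
#' signature is active, how total mutation burdens and per-signature
#' weights are drawn, and the noise model.
#'
#' Defaults state the benchmark world: 100 samples, per-sample burdens
#' log-uniform between 1e3 and 10^4.5 mutations (whole-genome scale,
#' above the 1000-mutation filter), Dirichlet-distributed weights over
#' the active signatures, and pure Poisson counts.
#'
#' @param signatures S x 96 non-negative matrix, rows summing to 1.
#' @param background_row Name or index of the designated background row
#'   (always active in every sample); `NA` for no background row.
#' @param n_samples Number of samples (default 100).
#' @param presence_fraction Per-signature probability that a sample is
#'   exposed to it, recycled to S; the background row is forced to 1.
#' @param burden_range Bounds of the log-uniform per-sample total
#'   mutation count (default `c(1e3, 10^4.5)`).
#' @param concentration Dirichlet concentration per signature (recycled
#'   to S). The default gives the background twice the weight of each
#'   other signature, mimicking its dominance in real genomes.
#' @param noise `"none"`, `"additive"`, or `"additive_subtractive"`:
#'   extra perturbation applied on top of Poisson sampling.
#' @param noise_rate Magnitude of the extra noise, as a multiple of the
#'   mean expected cell value (default 0.1).
#' @param noise_cell_fraction Fraction of cells perturbed per direction
#'   (default 0.1).
#' @param name Label for the spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(signatures, background_row = "Background",
                            n_samples = 100,
                            presence_fraction = 1,
                            burden_range = c(1e3, 10^4.5),
                            concentration = NULL,
                            noise = c("none", "additive", "additive_subtractive"),
                            noise_rate = 0.1, noise_cell_fraction = 0.1,
                            name = "custom") {
  noise <- match.arg(noise)
  stopifnot(is.matrix(signatures), ncol(signatures) == 96L,
            nrow(signatures) >= 1L, all(signatures >= 0))
  if (is.null(rownames(signatures))) {
    rownames(signatures) <- paste0("Signature_", seq_len(nrow(signatures)))
  }
  signatures <- signatures / rowSums(signatures)
  S <- nrow(signatures)
  bg <- if (length(background_row) == 1L && !is.na(background_row)) {
    i <- if (is.character(background_row)) {
      match(background_row, rownames(signatures))
    } else as.integer(background_row)
    if (is.na(i) || i < 1L || i > S) {
      stop("background_row not found in signatures", call. = FALSE)
    }
    i
  } else NA_integer_
  presence <- rep_len(presence_fraction, S)
  if (any(presence <= 0 | presence > 1)) {
    stop("presence fractions must be in (0, 1]", call. = FALSE)
  }
  if (!is.na(bg)) presence[bg] <- 1
  if (is.null(concentration)) {
    concentration <- rep(1.5, S)
    if (!is.na(bg)) concentration[bg] <- 3
  }
  concentration <- rep_len(concentration, S)
  stopifnot(length(burden_range) == 2L, burden_range[1] > 0,
            burden_range[2] >= burden_range[1], noise_rate >= 0)
  structure(list(signatures = signatures, background_row = bg,
                 n_samples = as.integer(n_samples), presence = presence,
                 burden_range = burden_range, concentration = concentration,
                 noise = noise, noise_rate = noise_rate,
                 noise_cell_fraction = noise_cell_fraction, name = name),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec '%s': %d samples, %d signatures%s\n",
              x$name, x$n_samples, nrow(x$signatures),
              if (!is.na(x$background_row))
                sprintf(" (background: %s)",
                        rownames(x$signatures)[x$background_row]) else ""))
  cat(sprintf("  burden: log-uniform [%g, %g]; noise: %s\n",
              x$burden_range[1], x$burden_range[2], x$noise))
  invisible(x)
}

#' Draw per-sample exposures
#'
#' For each sample, each signature is switched on independently with its
#' presence fraction (the background row is always on); the weights of
#' the active signatures are drawn from a Dirichlet with the spec's
#' concentrations and scaled so the exposure row sums to the sample's
#' log-uniform burden. A sample drawing no active signature is redrawn
#' (bounded retries).
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return List with `alpha0` (background exposures, or `NULL` when the
#'   spec has no background row) and `alpha` (exposures to the remaining
#'   signatures), plus `burdens` and the logical activity matrix
#'   `active`.
#' @export
generate_exposures <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(seed, {
    S <- nrow(spec$signatures)
    n <- spec$n_samples
    burdens <- 10^stats::runif(n, log10(spec$burden_range[1]),
                               log10(spec$burden_range[2]))
    expo <- matrix(0, n, S,
                   dimnames = list(paste0("Sample_", seq_len(n)),
                                   rownames(spec$signatures)))
    active <- matrix(FALSE, n, S, dimnames = dimnames(expo))
    for (i in seq_len(n)) {
      act <- logical(S)
      for (try in seq_len(100L)) {
        act <- stats::runif(S) < spec$presence
        if (any(act)) break
      }
      if (!any(act)) stop("no active signature after 100 retries", call. = FALSE)
      w <- .rdirichlet(1L, spec$concentration[act])[1L, ]
      expo[i, act] <- w * burdens[i]
      active[i, ] <- act
    }
    bg <- spec$background_row
    if (!is.na(bg)) {
      list(alpha0 = expo[, bg], alpha = expo[, -bg, drop = FALSE],
           burdens = burdens, active = active)
    } else {
      list(alpha0 = NULL, alpha = expo, burdens = burdens, active = active)
    }
  })
}

#' Sample mutation counts from exposures and signatures
#'
#' Each cell of the expected matrix `alpha %*% signatures` is sampled
#' from a Poisson with that mean (`counts_model = "poisson"`), or passed
#' through exactly (`"expected"`, for noiseless algebraic tests). The
#' optional extra noise perturbs a random subset of cells: additive
#' noise adds `Poisson(noise_rate * mean cell value)` counts, and the
#' subtractive component removes counts the same way, flooring at zero.
#'
#' @param exposures N x S non-negative matrix (all generating signatures
#'   in columns, background included).
#' @param signatures S x 96 matrix matching the exposure columns.
#' @param noise,noise_rate,noise_cell_fraction See [simulation_spec()].
#' @param counts_model `"poisson"` or `"expected"`.
#' @param seed Integer seed.
#' @return N x 96 count matrix (integer for `"poisson"`).
#' @export
simulate_counts <- function(exposures, signatures,
                            noise = c("none", "additive", "additive_subtractive"),
                            noise_rate = 0.1, noise_cell_fraction = 0.1,
                            counts_model = c("poisson", "expected"),
                            seed = NULL) {
  noise <- match.arg(noise)
  counts_model <- match.arg(counts_model)
  stopifnot(ncol(exposures) == nrow(signatures), noise_rate >= 0)
  mu <- exposures %*% signatures
  .with_seed(seed, {
    counts <- if (counts_model == "expected") mu else {
      matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
    }
    if (noise != "none" && noise_rate > 0) {
      mean_cell <- mean(mu)
      n_cells <- length(counts)
      n_pert <- ceiling(noise_cell_fraction * n_cells)
      add_cells <- sample.int(n_cells, n_pert)
      counts[add_cells] <- counts[add_cells] +
        stats::rpois(n_pert, noise_rate * mean_cell)
      if (noise == "additive_subtractive") {
        sub_cells <- sample.int(n_cells, n_pert)
        counts[sub_cells] <- pmax(
          0, counts[sub_cells] - stats::rpois(n_pert, noise_rate * mean_cell))
      }
    }
    dimnames(counts) <- list(rownames(exposures), mutation_categories())
    counts
  })
}

#' Generate a complete synthetic dataset
#'
#' Draws exposures and counts in one deterministic step and keeps the
#' ground truth for evaluation.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed; identical spec and seed give an identical
#'   dataset.
#' @param counts_model Passed to [simulate_counts()].
#' @return List with `counts` (N x 96), `true_signatures` (non-background
#'   rows), `true_exposures` (N x K), `true_background`,
#'   `true_alpha0`, `active`, and the `spec`.
#' @export
simulate_dataset <- function(spec, seed = NULL,
                             counts_model = c("poisson", "expected")) {
  counts_model <- match.arg(counts_model)
  expo <- generate_exposures(spec, seed = if (is.null(seed)) NULL
                                          else .derive_seed(seed, 1L))
  bg <- spec$background_row
  full_expo <- if (!is.na(bg)) {
    cbind(expo$alpha, matrix(expo$alpha0, ncol = 1,
                             dimnames = list(NULL, rownames(spec$signatures)[bg])))
  } else expo$alpha
  sig_order <- colnames(full_expo)
  counts <- simulate_counts(full_expo, spec$signatures[sig_order, , drop = FALSE],
                            noise = spec$noise, noise_rate = spec$noise_rate,
                            noise_cell_fraction = spec$noise_cell_fraction,
                            counts_model = counts_model,
                            seed = if (is.null(seed)) NULL
                                   else .derive_seed(seed, 2L))
  storage.mode(counts) <- if (counts_model == "poisson") "integer" else "double"
  list(counts = counts,
       true_signatures = if (!is.na(bg))
         spec$signatures[-bg, , drop = FALSE] else spec$signatures,
       true_exposures = expo$alpha,
       true_background = if (!is.na(bg)) spec$signatures[bg, ] else NULL,
       true_alpha0 = expo$alpha0,
       active = expo$active,
       spec = spec)
}

#' Benchmark simulation presets
#'
#' Fully populated [simulation_spec()]s reproducing the statistical
#' structure of the six published benchmark designs:
#'
#' * `sim1` — 116 samples, the fixed dense background plus three
#'   well-separated sparse signatures, pure Poisson counts.
#' * `sim2` — as `sim1` with additive and subtractive noise.
#' * `sim3` — 100 samples, background plus 3 signatures drawn at random
#'   from the catalog, with random presence fractions in (0.2, 1] so
#'   some signatures are rare.
#' * `sim4` — as `sim3` restricted to dense catalog signatures (>75% of
#'   categories contributing).
#' * `sim5` — as `sim3` restricted to sparse catalog signatures (<50%
#'   contributing).
#' * `sim6` — 100 samples, background plus 7 random catalog signatures
#'   (8 in total).
#'
#' Random choices made by a preset (which catalog rows, which presence
#' fractions) are resolved at construction using `seed`, so the returned
#' spec is concrete and reproducible.
#'
#' @param name `"sim1"` .. `"sim6"`.
#' @param catalog Optional signature matrix (rows summing to 1) to draw
#'   non-background signatures from, e.g. an external catalog read with
#'   [read_signature_matrix()]; defaults to the packaged
#'   [synthetic_catalog()].
#' @param background Background signature used as the designated
#'   background row (default the germline preset).
#' @param seed Integer seed resolving the preset's random choices.
#' @param contribution_threshold Probability above which a category
#'   counts as contributing, for the dense/sparse split (default 1/960,
#'   i.e. 1% of the uniform rate).
#' @return A [simulation_spec()].
#' @examples
#' simulation_preset("sim1")
#' @export
simulation_preset <- function(name = c("sim1", "sim2", "sim3", "sim4",
                                       "sim5", "sim6"),
                              catalog = NULL,
                              background = load_background_preset("germline"),
                              seed = 1,
                              contribution_threshold = 1 / 960) {
  name <- match.arg(name)
  if (is.null(catalog)) catalog <- synthetic_catalog()
  stopifnot(is.matrix(catalog), ncol(catalog) == 96L)
  catalog <- catalog / rowSums(catalog)
  sigs_with_bg <- function(rows) {
    m <- rbind(Background = as.numeric(background),
               catalog[rows, , drop = FALSE])
    colnames(m) <- mutation_categories()
    m
  }
  frac <- .contribution_fraction(catalog, contribution_threshold)

  if (name %in% c("sim1", "sim2")) {
    # the fixed design: three designated sparse profiles
    rows <- c("SYN-S1", "SYN-S2", "SYN-S3")
    if (!all(rows %in% rownames(catalog))) {
      sparse_rows <- rownames(catalog)[frac < 0.5]
      if (length(sparse_rows) < 3L) {
        stop("catalog has fewer than 3 sparse signatures for ", name,
             call. = FALSE)
      }
      rows <- sparse_rows[1:3]
    }
    return(simulation_spec(
      sigs_with_bg(rows), background_row = "Background", n_samples = 116,
      presence_fraction = 1,
      noise = if (name == "sim2") "additive_subtractive" else "none",
      name = name
    ))
  }

  pick <- function(pool, k) {
    if (length(pool) < k) {
      stop("catalog has only ", length(pool), " eligible signatures; ",
           k, " needed for ", name, call. = FALSE)
    }
    sample(pool, k)
  }
  .with_seed(seed, {
    if (name == "sim3") {
      rows <- pick(rownames(catalog), 3L)
      presence <- c(1, stats::runif(3L, 0.2, 1))
    } else if (name == "sim4") {
      rows <- pick(rownames(catalog)[frac > 0.75], 3L)
      presence <- c(1, stats::runif(3L, 0.2, 1))
    } else if (name == "sim5") {
      rows <- pick(rownames(catalog)[frac < 0.5], 3L)
      presence <- c(1, stats::runif(3L, 0.2, 1))
    } else { # sim6
      rows <- pick(rownames(catalog), 7L)
      presence <- c(1, stats::runif(7L, 0.2, 1))
    }
    simulation_spec(sigs_with_bg(rows), background_row = "Background",
                    n_samples = 100, presence_fraction = presence,
                    name = name)
  })
}
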