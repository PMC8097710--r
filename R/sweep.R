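#' Validation sweep specification
#'
#' Describes a paired comparison of rendering methods over a grid of
#' modulation depths: for each depth, a number of independent stimulus
#' exemplars is generated (fresh carriers and a fresh random envelope phase
#' per exemplar), rendered with each requested method from the *same* draws,
#' and summarized by spectral-envelope metrics. Depths are peak-to-valley dB
#' values; the default grid spans 0-50 dB in 20 steps. Modulation is spectral
#' (rate 0) at 2 cycles/octave by default, so the envelope can be read off
#' the spectrum.
#'
#' @param depths_pv_db Peak-to-valley modulation depths in dB.
#' @param n_exemplars Exemplars per depth, `>= 1`.
#' @param methods Subset of `c("sideband", "explicit")`.
#' @param density Spectral modulation density in cycles/octave.
#' @param rate Temporal modulation rate in Hz (0 for SM, the validation
#'   geometry).
#' @param tolerance_db Energy-deficiency budget used to pick the sideband
#'   extent at each depth.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(depths_pv_db = seq(0, 50, length.out = 20),
                       n_exemplars = 100,
                       methods = c("sideband", "explicit"),
                       density = 2, rate = 0, tolerance_db = 1e-8) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(depths_pv_db < 0)) stop_domain("depths must be non-negative dB")
  if (n_exemplars < 1) stop_domain("'n_exemplars' must be >= 1")
  structure(
    list(depths_pv_db = as.numeric(depths_pv_db),
         n_exemplars = as.integer(n_exemplars), methods = methods,
         density = density, rate = rate, tolerance_db = tolerance_db),
    class = "sweep_spec"
  )
}

#' Run a paired method-validation sweep
#'
#' For every (depth, exemplar) cell: draw a band-shaped random carrier set
#' and a random envelope starting phase, render the spectrally modulated
#' stimulus with each method from those shared draws, and compute the
#' normalized fourth moment and crest factor of the in-band spectral
#' envelope. Seeding is hierarchical — a master seed spawns one stream per
#' cell — so methods see identical carriers and the sweep is reproducible.
#'
#' @param noise A [noise_spec()] (its own `seed` field is ignored here; the
#'   sweep's master seed governs).
#' @param sweep A [sweep_spec()].
#' @param config A [render_config()]; `seed` is the master seed (default 1).
#' @return An `stm_sweep` data frame in long format with columns `depth_db`
#'   (peak-to-valley), `method`, `exemplar`, `m4`, `crest_factor`.
#'   `summary()` aggregates per-depth means and standard deviations.
#' @export
run_validation_sweep <- function(noise, sweep, config) {
  stopifnot(inherits(noise, "noise_spec"), inherits(sweep, "sweep_spec"),
            inherits(config, "render_config"))
  master <- config$seed %||% 1L
  noise$seed <- NULL  # the per-cell streams below govern all draws
  band <- c(noise$band_lo, noise$band_hi)
  rows <- vector("list", length(sweep$depths_pv_db) * sweep$n_exemplars)
  i <- 0L
  for (d in seq_along(sweep$depths_pv_db)) {
    depth_pv <- sweep$depths_pv_db[d]
    m <- depth_pv / 2  # midpoint-to-peak, the depth convention of I_k(M')
    K <- if (m > 0) min_extent_for_tolerance(m, sweep$tolerance_db) else 0L
    for (e in seq_len(sweep$n_exemplars)) {
      set.seed((master + 7919L * d + e) %% .Machine$integer.max)
      carriers <- generate_noise_carriers(noise, config)
      phase0 <- runif(1, 0, 2 * pi)
      params <- modulation_params(
        if (m > 0) "exponential" else "none",
        depth = if (m > 0) m else NULL,
        rate = sweep$rate, density = sweep$density,
        phase0 = phase0, f_ref = noise$band_lo)
      res <- lapply(sweep$methods, function(meth) {
        cfg <- config
        cfg$method <- meth
        cfg$extent <- K
        cfg$tolerance_db <- NULL
        w <- render_stm(carriers, params, cfg)
        env <- spectral_envelope(w, band)
        data.frame(depth_db = depth_pv, method = meth, exemplar = e,
                   m4 = normalized_fourth_moment(env),
                   crest_factor = crest_factor(env),
                   stringsAsFactors = FALSE)
      })
      i <- i + 1L
      rows[[i]] <- do.call(rbind, res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("stm_sweep", "data.frame"))
}

#' @export
summary.stm_sweep <- function(object, ...) {
  agg <- function(v) {
    a <- stats::aggregate(object[[v]],
                          by = list(depth_db = object$depth_db,
                                    method = object$method),
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
    data.frame(depth_db = a$depth_db, method = a$method,
               mean = a$x[, "mean"], sd = a$x[, "sd"],
               metric = v, stringsAsFactors = FALSE)
  }
  out <- rbind(agg("m4"), agg("crest_factor"))
  out[order(out$metric, out$method, out$depth_db), ]
}

#' @export
print.stm_sweep <- function(x, ...) {
  cat(sprintf("Validation sweep: %d rows (%d depths x %d exemplars x %d methods)\n",
              nrow(x), length(unique(x$depth_db)),
              max(x$exemplar), length(unique(x$method))))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
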