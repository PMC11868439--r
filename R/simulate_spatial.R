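#' Configuration for the spatial cellbin generator
#'
#' Defines a 2-D rectangular window (micrometer-like units) containing a
#' Thomas cluster process of cholangiocytes (Poisson parents, Poisson
#' offspring displaced by an isotropic Gaussian), LPCs attracted to the same
#' parents (Gaussian displacement of scale `lpc_attraction_sd`), and uniform
#' background cell types. This emulates the observed geometry in which liver
#' progenitors sit close to cholangiocyte structures while hepatocytes,
#' endothelial cells and stellate cells fill the parenchyma.
#'
#' @param window c(xmin, xmax, ymin, ymax) extent of the tissue window.
#' @param type_intensities named expected counts per unit area for the
#'   uniform background types (e.g. hepatocyte, endothelial, HSC,
#'   macrophage).
#' @param lpc_intensity expected LPCs per unit area.
#' @param chol_parent_intensity expected cholangiocyte cluster centres
#'   (e.g. bile-duct structures) per unit area.
#' @param chol_offspring_mean expected cholangiocytes per cluster centre.
#' @param chol_offspring_sd Gaussian spread of cholangiocytes around their
#'   centre.
#' @param lpc_attraction_sd Gaussian displacement scale of LPCs around a
#'   random cholangiocyte cluster centre; must be >= 0 (0 places every LPC
#'   exactly on a centre).
#' @param seed integer seed.
#' @return A list of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(window = c(0, 1000, 0, 1000),
                               type_intensities = c(hepatocyte = 6e-4,
                                                    endothelial = 2e-4,
                                                    HSC = 1.5e-4,
                                                    macrophage = 1.5e-4),
                               lpc_intensity = 5e-5,
                               chol_parent_intensity = 1e-5,
                               chol_offspring_mean = 15,
                               chol_offspring_sd = 25,
                               lpc_attraction_sd = 25,
                               seed = 1L) {
  if (length(window) != 4 || window[2] <= window[1] || window[4] <= window[3]) {
    stop_lpc("window must be c(xmin, xmax, ymin, ymax) with positive area")
  }
  if (any(type_intensities < 0) || lpc_intensity < 0 ||
      chol_parent_intensity < 0) {
    stop_lpc("intensities must be nonnegative")
  }
  chk_scalar(lpc_attraction_sd, "lpc_attraction_sd", 0)
  chk_scalar(chol_offspring_sd, "chol_offspring_sd", 0)
  structure(as.list(environment()), class = "spatial_sim_config")
}

# draw n Gaussian displacements around centres, resampling any that land
# outside the window (keeps the cluster geometry without edge pile-up)
displace_inside <- function(cx, cy, sd, window, max_tries = 100) {
  n <- length(cx)
  x <- cx + stats::rnorm(n, sd = sd)
  y <- cy + stats::rnorm(n, sd = sd)
  for (t in seq_len(max_tries)) {
    out <- x < window[1] | x > window[2] | y < window[3] | y > window[4]
    if (!any(out)) break
    x[out] <- cx[out] + stats::rnorm(sum(out), sd = sd)
    y[out] <- cy[out] + stats::rnorm(sum(out), sd = sd)
  }
  # pathological sd relative to window: clamp the stragglers
  x <- pmin(pmax(x, window[1]), window[2])
  y <- pmin(pmax(y, window[3]), window[4])
  cbind(x, y)
}

#' Simulate a spatial cellbin map with planted LPC attraction
#'
#' @param config a [spatial_sim_config()].
#' @return A `spatial_map`: data.frame with columns `cell_id`, `x`, `y`,
#'   `cell_type`, plus attribute `window`.
#' @examples
#' m <- simulate_spatial(spatial_sim_config(seed = 3))
#' table(m$cell_type)
#' @export
simulate_spatial <- function(config = spatial_sim_config()) {
  stopifnot(inherits(config, "spatial_sim_config"))
  cfg <- config
  w <- cfg$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  local_seed(cfg$seed, {
    # cholangiocyte parents; re-drawn (never silently empty) if LPCs need them
    n_par <- stats::rpois(1, cfg$chol_parent_intensity * area)
    tries <- 0L
    while (n_par == 0 && cfg$lpc_intensity > 0 && tries < 100L) {
      n_par <- stats::rpois(1, cfg$chol_parent_intensity * area)
      tries <- tries + 1L
    }
    if (n_par == 0 && cfg$lpc_intensity > 0) {
      n_par <- 1L  # guaranteed anchor after repeated empty draws
    }
    if (tries > 0L) {
      message(sprintf("cholangiocyte parent draw regenerated %d time(s)", tries))
    }
    px <- stats::runif(n_par, w[1], w[2])
    py <- stats::runif(n_par, w[3], w[4])

    xs <- numeric(0); ys <- numeric(0); tp <- character(0)
    if (n_par > 0) {
      n_off <- stats::rpois(n_par, cfg$chol_offspring_mean)
      par_idx <- rep(seq_len(n_par), n_off)
      if (length(par_idx) > 0) {
        xy <- displace_inside(px[par_idx], py[par_idx],
                              cfg$chol_offspring_sd, w)
        xs <- c(xs, xy[, 1]); ys <- c(ys, xy[, 2])
        tp <- c(tp, rep("cholangiocyte", length(par_idx)))
      }
    }
    n_lpc <- stats::rpois(1, cfg$lpc_intensity * area)
    if (n_lpc > 0) {
      par_idx <- sample.int(n_par, n_lpc, replace = TRUE)
      xy <- displace_inside(px[par_idx], py[par_idx], cfg$lpc_attraction_sd, w)
      xs <- c(xs, xy[, 1]); ys <- c(ys, xy[, 2])
      tp <- c(tp, rep("LPC", n_lpc))
    }
    for (t in names(cfg$type_intensities)) {
      n_t <- stats::rpois(1, cfg$type_intensities[[t]] * area)
      xs <- c(xs, stats::runif(n_t, w[1], w[2]))
      ys <- c(ys, stats::runif(n_t, w[3], w[4]))
      tp <- c(tp, rep(t, n_t))
    }
    out <- data.frame(cell_id = sprintf("bin%05d", seq_along(xs)),
                      x = xs, y = ys, cell_type = tp,
                      stringsAsFactors = FALSE)
    attr(out, "window") <- w
    class(out) <- c("spatial_map", "data.frame")
    out
  })
}
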