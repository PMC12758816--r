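# Fast-subsystem analysis: the (V, x_D) dynamics with the slow ion
# concentrations frozen as parameters. Because x_D relaxes to
# x_D*(V) = 1 / (1 + tau_x * delta_x * nu(V)), equilibria reduce to the
# roots of the scalar residual f(V) = u(V, x_D*(V), K_o) - V, found by
# dense sign-change bracketing plus root refinement.

fast_xD_star <- function(V, params) {
  1 / (1 + params$tau_x * params$delta_x * firing_rate(V, params))
}

fast_residual <- function(V, K_o, params) {
  membrane_drive(V, fast_xD_star(V, params), K_o, params) - V
}

# 2x2 Jacobian of the (V, x_D) fast subsystem at a point.
fast_jacobian <- function(V, x_D, K_o, params) {
  nu <- firing_rate(V, params)
  dnu <- nu * (1 - nu / params$nu_max)      # d nu / dV, per mV
  du_dV <- params$g_exc_rel * dnu * x_D - params$g_inh_rel
  du_dx <- params$g_exc_rel * nu
  matrix(c((du_dV - 1) / params$tau_m, du_dx / params$tau_m,
           -params$delta_x * x_D * dnu,
           -1 / params$tau_x - params$delta_x * nu),
         2, 2, byrow = TRUE)
}

classify_stability <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  complex_pair <- is.complex(ev) && any(abs(Im(ev)) > 1e-12)
  if (all(re < 0)) if (complex_pair) "stable-focus" else "stable-node"
  else if (all(re > 0)) if (complex_pair) "unstable-focus" else "unstable-node"
  else "saddle"
}

#' Fast-subsystem equilibria at a frozen potassium level
#'
#' Finds all equilibria of the fast (V, x_D) subsystem with the
#' extracellular potassium frozen at `K_o` (the intracellular sodium does
#' not enter the fast subsystem). Roots are bracketed by sign changes on
#' a dense membrane-potential grid and refined to high precision;
#' stability follows from the eigenvalues of the 2x2 Jacobian.
#'
#' @param K_o Frozen extracellular potassium (mM), positive.
#' @param params An [epi_params()] object.
#' @param V_range Scan range for the membrane potential (mV).
#' @param n_grid Number of scan points.
#' @return Data frame with columns `V`, `x_D`, `stability`, `re1`, `re2`
#'   (eigenvalue real parts), `residual`; ordered by `V`.
#' @export
equilibria_at <- function(K_o, params, V_range = c(-30, 60),
                          n_grid = 2000L) {
  stopifnot(K_o > 0)
  Vg <- seq(V_range[1], V_range[2], length.out = n_grid)
  fg <- fast_residual(Vg, K_o, params)
  sgn <- sign(fg)
  roots <- Vg[fg == 0]
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (i in idx) {
    r <- stats::uniroot(fast_residual, c(Vg[i], Vg[i + 1]), K_o = K_o,
                        params = params, tol = 1e-13)$root
    # Newton polish
    for (k in 1:3) {
      f0 <- fast_residual(r, K_o, params)
      fp <- (fast_residual(r + 1e-7, K_o, params) - f0) / 1e-7
      if (abs(fp) > 1e-12) r <- r - f0 / fp
    }
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) return(data.frame(V = numeric(0), x_D = numeric(0),
                                        stability = character(0),
                                        re1 = numeric(0), re2 = numeric(0),
                                        residual = numeric(0)))
  rows <- lapply(roots, function(V) {
    x <- fast_xD_star(V, params)
    J <- fast_jacobian(V, x, K_o, params)
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(V = V, x_D = x, stability = classify_stability(J),
               re1 = Re(ev[1]), re2 = Re(ev[2]),
               residual = fast_residual(V, K_o, params))
  })
  do.call(rbind, rows)
}

#' Trace fast-subsystem equilibrium branches and bifurcation points
#'
#' Scans a potassium grid, assembles the S-shaped equilibrium branch
#' structure, and locates the two folds and the Hopf point by bisection:
#' `LP2` (lower fold, where the depolarized branch is born), `HB1` (Hopf
#' on the depolarized branch, mediating seizure termination) and `LP1`
#' (upper fold, the potassium seizure threshold), with
#' `K(LP2) < K(HB1) < K(LP1)`. The bistable (hysteresis) window is
#' `(K(LP2), K(LP1))`. The frozen sodium concentration plays no role in
#' the fast subsystem.
#'
#' @param params An [epi_params()] object.
#' @param K_grid Potassium scan grid (mM); must span the fold window.
#' @param V_range Membrane-potential scan range (mV).
#' @param tol Bisection tolerance for fold/Hopf potassium values (mM).
#' @return An object of class `epi_bifurcation`: list with `branch` (data
#'   frame `K_o`, `V`, `x_D`, `stability`) and `points` (named list
#'   `LP1`, `LP2`, `HB1`, each with `K_o` and `V`).
#' @export
trace_branches <- function(params, K_grid = seq(0.5, 12, by = 0.025),
                           V_range = c(-30, 60), tol = 1e-4) {
  counts <- integer(length(K_grid))
  branch <- vector("list", length(K_grid))
  for (i in seq_along(K_grid)) {
    eq <- equilibria_at(K_grid[i], params, V_range)
    counts[i] <- nrow(eq)
    if (nrow(eq)) branch[[i]] <- cbind(K_o = K_grid[i], eq)
  }
  branch <- do.call(rbind, branch)

  n_roots <- function(K) nrow(equilibria_at(K, params, V_range))
  bisect_count <- function(lo, hi) {
    clo <- n_roots(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (n_roots(mid) == clo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  chg <- which(diff(counts) != 0)
  if (length(chg) < 2)
    stop("folds not bracketed by K_grid: root counts ",
         paste(unique(counts), collapse = "/"),
         "; widen the grid")
  folds <- vapply(chg, function(i) bisect_count(K_grid[i], K_grid[i + 1]),
                  numeric(1))
  # LP2 = fold at lowest K (birth of the depolarized pair), LP1 = highest
  K_lp2 <- min(folds); K_lp1 <- max(folds)
  fold_V <- function(K) {
    # V of the merging pair just inside the 3-root window
    eps <- 5 * tol
    K_in <- if (K == K_lp2) K + eps else K - eps
    eq <- equilibria_at(K_in, params, V_range)
    if (nrow(eq) >= 3) {
      if (K == K_lp2) mean(eq$V[2:3]) else mean(eq$V[1:2])
    } else NA_real_
  }

  # Hopf on the depolarized (highest-V) branch: sign change of the real
  # part of the complex eigenvalue pair.
  upper_re <- function(K) {
    eq <- equilibria_at(K, params, V_range)
    i <- which.max(eq$V)
    max(eq$re1[i], eq$re2[i])
  }
  K_scan <- K_grid[K_grid > K_lp2 + tol]
  res <- vapply(K_scan, upper_re, numeric(1))
  sgn_chg <- which(res[-1] * res[-length(res)] < 0)
  if (!length(sgn_chg))
    stop("Hopf point not bracketed on the depolarized branch")
  lo <- K_scan[sgn_chg[1]]; hi <- K_scan[sgn_chg[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (upper_re(mid) * upper_re(lo) > 0) lo <- mid else hi <- mid
  }
  K_hb1 <- (lo + hi) / 2
  eq_hb <- equilibria_at(K_hb1, params, V_range)
  V_hb <- eq_hb$V[which.max(eq_hb$V)]

  points <- list(LP1 = list(K_o = K_lp1, V = fold_V(K_lp1)),
                 LP2 = list(K_o = K_lp2, V = fold_V(K_lp2)),
                 HB1 = list(K_o = K_hb1, V = V_hb))
  structure(list(branch = branch, points = points, params = params),
            class = "epi_bifurcation")
}

#' @export
print.epi_bifurcation <- function(x, ...) {
  p <- x$points
  cat(sprintf("Fast-subsystem bifurcation structure:\n  LP2 at K_o = %.4f mM, HB1 at %.4f mM, LP1 at %.4f mM\n",
              p$LP2$K_o, p$HB1$K_o, p$LP1$K_o))
  cat(sprintf("  bistable window: (%.4f, %.4f) mM\n", p$LP2$K_o, p$LP1$K_o))
  invisible(x)
}

#' Classify a potassium level as ictal or interictal
#'
#' Below the lower fold `LP2` the system is interictal regardless of
#' history; above the upper fold `LP1` it is ictal. Inside the bistable
#' window the regime is set by history (hysteresis).
#'
#' @param K_o Extracellular potassium (mM).
#' @param points The `points` element of [trace_branches()] (or the
#'   `epi_bifurcation` object itself).
#' @param history `"coming-from-interictal"` or `"coming-from-ictal"`.
#' @return `"ictal"` or `"interictal"`.
#' @export
classify_region <- function(K_o, points,
                            history = c("coming-from-interictal",
                                        "coming-from-ictal")) {
  history <- match.arg(history)
  if (inherits(points, "epi_bifurcation")) points <- points$points
  if (K_o < points$LP2$K_o) "interictal"
  else if (K_o > points$LP1$K_o) "ictal"
  else if (history == "coming-from-ictal") "ictal" else "interictal"
}

#' Slow-passage trajectory hugging the equilibrium surface
#'
#' Integrates the full model with the potassium and sodium equations
#' scaled by a small factor `epsilon`, so the trajectory tracks the
#' fast-subsystem equilibrium branches and jumps between them near the
#' bifurcation points: up near the upper fold `LP1`, down near the Hopf
#' point `HB1`. `epsilon = 1` recovers the standard model exactly.
#'
#' @param params An [epi_params()] object.
#' @param epsilon Slow-scaling factor in (0, 1].
#' @param t_end Simulation length (s); at `epsilon = 0.003` one full
#'   cycle takes several thousand seconds.
#' @param dt Integration step (s).
#' @param init Initial state; default starts on the low-potassium
#'   (interictal) branch.
#' @param V_mid Membrane-potential level separating the low and
#'   depolarized branches for jump detection (mV).
#' @return List with `trajectory`, `K_jump_up` and `K_jump_down` (mM;
#'   `NA` when the corresponding jump does not occur within `t_end`).
#' @export
overlay_slow_trajectory <- function(params, epsilon = 0.003, t_end = 30000,
                                    dt = 2e-4, init = NULL, V_mid = 8) {
  if (is.null(init))
    init <- c(V = 0, x_D = 1, K_o = params$K_o0, Na_i = params$Na_i0)
  traj <- simulate_epileptor(params, t_end = t_end, dt = dt, init = init,
                             epsilon = epsilon, record_dt = 0.05)
  up <- which(traj$V[-1] > V_mid & traj$V[-length(traj$V)] <= V_mid)
  down <- which(traj$V[-1] < V_mid & traj$V[-length(traj$V)] >= V_mid)
  K_up <- if (length(up)) traj$K_o[up[1]] else NA_real_
  K_down <- if (length(up) && any(down > up[1]))
    traj$K_o[down[down > up[1]][1]] else NA_real_
  list(trajectory = traj, K_jump_up = K_up, K_jump_down = K_down)
}

#' Write bifurcation branches and points to CSV/JSON
#'
#' @param x An `epi_bifurcation` object.
#' @param branch_csv Path for the branch table (CSV).
#' @param points_json Optional path for the bifurcation points (JSON).
#' @export
write_bifurcation <- function(x, branch_csv, points_json = NULL) {
  utils::write.csv(x$branch, branch_csv, row.names = FALSE)
  if (!is.null(points_json))
    jsonlite::write_json(x$points, points_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(x)
}
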