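#' Three-element Windkessel parameters
#'
#' Proximal resistance R_p, distal resistance R_d (Pa s/m^3), compliance C
#' (m^3/Pa) and distal reference pressure (Pa). The boundary obeys
#' P = P_c + R_p Q with state law C dP_c/dt = Q - (P_c - P_ref)/R_d.
#'
#' @param R_p,R_d resistances (Pa s/m^3), positive.
#' @param C compliance (m^3/Pa), positive.
#' @param P_ref distal reference pressure (Pa), default 0.
#' @return object of class `wk3_params`.
#' @export
wk3_params <- function(R_p, R_d, C, P_ref = 0) {
  if (R_p <= 0 || R_d <= 0 || C <= 0) stop("R_p, R_d and C must be positive")
  structure(list(type = "wk3", R_p = R_p, R_d = R_d, C = C, P_ref = P_ref),
            class = "wk3_params")
}

#' Fixed-pressure (venous) termination
#'
#' @param value static pressure (Pa), e.g. `mmHg_to_Pa(8)` for a central
#'   venous pressure of 8 mmHg.
#' @return termination descriptor.
#' @export
pressure_sink <- function(value) {
  list(type = "pressure", value = value)
}

#' Prescribed-inflow termination marker
#'
#' Marks the single node at which the inflow waveform (supplied to
#' [simulate_network()]) is injected.
#' @return termination descriptor.
#' @export
inflow_marker <- function() list(type = "inflow")

#' Lumped-parameter (0D) vascular network
#'
#' Directed graph of resistor--inductor segments. Each segment carries the
#' pressure-drop law dP = a Q|Q| + b Q + L dQ/dt (the quadratic term is
#' written a Q|Q| so the drop opposes reversed flow). Boundary nodes are
#' terminated by a prescribed inflow (exactly one), three-element Windkessel
#' models, or fixed pressure sinks.
#'
#' @param nodes character vector of node names.
#' @param segments data.frame with columns `name`, `from`, `to`, `a`
#'   (Pa s^2/m^6), `b` (Pa s/m^3), `L` (Pa s^2/m^3). Optional `l` (m) and
#'   `A` (m^2) are carried for bookkeeping.
#' @param terminations named list keyed by node name; values are
#'   [wk3_params()], [pressure_sink()] or [inflow_marker()].
#' @return object of class `network0d`.
#' @export
network0d <- function(nodes, segments, terminations) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("name", "from", "to", "a", "b", "L")
  if (!all(need %in% names(segments))) {
    stop("segments need columns: ", paste(need, collapse = ", "))
  }
  if (!all(segments$from %in% nodes) || !all(segments$to %in% nodes)) {
    stop("segment endpoints must be declared nodes")
  }
  if (any(segments$b < 0) || any(segments$L < 0)) {
    stop("b and L must be non-negative")
  }
  if (!all(names(terminations) %in% nodes)) {
    stop("termination on undeclared node")
  }
  types <- vapply(terminations, function(x) x$type, "")
  if (sum(types == "inflow") != 1L) stop("exactly one inflow node is required")
  # connectivity
  adj <- unique(rbind(cbind(segments$from, segments$to),
                      cbind(segments$to, segments$from)))
  reached <- nodes[1]
  repeat {
    nxt <- unique(adj[adj[, 1] %in% reached, 2])
    new <- setdiff(nxt, reached)
    if (!length(new)) break
    reached <- c(reached, new)
  }
  if (!setequal(reached, nodes)) stop("network is not connected")
  # every degree-1 node must be terminated
  deg <- table(c(segments$from, segments$to))
  leaves <- names(deg)[deg == 1]
  untermed <- setdiff(leaves, names(terminations))
  if (length(untermed)) {
    stop("boundary node(s) without termination: ",
         paste(untermed, collapse = ", "))
  }
  structure(list(nodes = nodes, segments = segments,
                 terminations = terminations),
            class = "network0d")
}

#' Least-squares fit of a zero-intercept quadratic resistance curve
#'
#' Fits dP = a Q^2 + b Q to sampled (flow, pressure-drop) pairs, typically
#' extracted from steady 3D simulations across the inflow range. The zero
#' intercept is enforced (no drop at no flow).
#'
#' @param flows flow rates (m^3/s), at least 2 distinct values.
#' @param pressure_drops pressure drops (Pa), same length.
#' @return list `a` (Pa s^2/m^6), `b` (Pa s/m^3), `residual_norm` (Pa).
#' @export
fit_quadratic_resistance <- function(flows, pressure_drops) {
  if (length(flows) != length(pressure_drops)) stop("length mismatch")
  if (length(unique(flows)) < 2L) stop("need at least 2 distinct flows")
  X <- cbind(flows^2, flows)
  if (qr(X)$rank < 2L) stop("rank-deficient design (flows do not separate a and b)")
  cf <- qr.solve(X, pressure_drops)
  res <- pressure_drops - X %*% cf
  list(a = unname(cf[1]), b = unname(cf[2]),
       residual_norm = sqrt(sum(res^2)))
}

#' Inertance of a vessel segment
#'
#' L = (4/3) rho l / A for a large artery of length l and cross-sectional
#' area A (flat-profile correction factor 4/3).
#'
#' @param l segment length (m), non-negative.
#' @param A cross-sectional area (m^2), positive.
#' @param rho blood density (kg/m^3), default 1056.
#' @return inertance (Pa s^2/m^3).
#' @export
segment_inertance <- function(l, A, rho = 1056) {
  if (any(A <= 0)) stop("area must be positive")
  if (any(l < 0)) stop("length must be non-negative")
  if (rho <= 0) stop("density must be positive")
  4 / 3 * rho * l / A
}

# --- solver internals -------------------------------------------------------

#' @keywords internal
build_solver <- function(net, dt) {
  nodes <- net$nodes
  seg <- net$segments
  term <- net$terminations
  types <- vapply(term, function(x) x$type, "")
  fixed_nodes <- names(term)[types == "pressure"]
  fixed_vals <- vapply(term[types == "pressure"], function(x) x$value, 0)
  inflow_node <- names(term)[types == "inflow"]
  wk3_nodes <- names(term)[types == "wk3"]
  wk3 <- term[wk3_nodes]

  free_nodes <- setdiff(nodes, fixed_nodes)
  nP <- length(free_nodes); nS <- nrow(seg); nW <- length(wk3_nodes)
  iP <- stats::setNames(seq_len(nP), free_nodes)
  # unknowns: [P_free, Q_seg, Pc_wk3]; equations: [balance_free, seg_law, wk3_state]
  n <- nP + nS + nW
  qcol <- nP + seq_len(nS)
  ccol <- nP + nS + seq_len(nW)

  from_free <- match(seg$from, free_nodes)   # NA if fixed
  to_free <- match(seg$to, free_nodes)
  from_fix <- fixed_vals[match(seg$from, fixed_nodes)]
  to_fix <- fixed_vals[match(seg$to, fixed_nodes)]
  from_fix[is.na(from_fix)] <- 0; to_fix[is.na(to_fix)] <- 0
  Ldt <- seg$L / dt
  wk_node_idx <- iP[wk3_nodes]               # wk3 nodes are never fixed
  Rp <- vapply(wk3, function(x) x$R_p, 0)
  Rd <- vapply(wk3, function(x) x$R_d, 0)
  Cc <- vapply(wk3, function(x) x$C, 0)
  Pref <- vapply(wk3, function(x) x$P_ref, 0)
  Cdt <- Cc / dt
  inflow_row <- iP[inflow_node]

  M0 <- matrix(0, n, n)
  # node balances (rows 1..nP): sum of segment flows signed into node
  for (j in seq_len(nS)) {
    if (!is.na(to_free[j]))   M0[to_free[j], qcol[j]] <- M0[to_free[j], qcol[j]] + 1
    if (!is.na(from_free[j])) M0[from_free[j], qcol[j]] <- M0[from_free[j], qcol[j]] - 1
  }
  for (w in seq_len(nW)) {
    r <- wk_node_idx[w]
    M0[r, r] <- M0[r, r] - 1 / Rp[w]          # - (P - Pc)/Rp term, d/dP
    M0[r, ccol[w]] <- M0[r, ccol[w]] + 1 / Rp[w]
  }
  # segment laws (rows nP+1..nP+nS)
  for (j in seq_len(nS)) {
    r <- nP + j
    if (!is.na(from_free[j])) M0[r, from_free[j]] <- 1
    if (!is.na(to_free[j]))   M0[r, to_free[j]] <- -1
    # dQ entry depends on |Q|; base part:
    M0[r, qcol[j]] <- -(seg$b[j] + Ldt[j])
  }
  # wk3 state laws (rows nP+nS+1..n)
  for (w in seq_len(nW)) {
    r <- nP + nS + w
    M0[r, ccol[w]] <- Cdt[w] + 1 / Rp[w] + 1 / Rd[w]
    M0[r, wk_node_idx[w]] <- -1 / Rp[w]
  }

  list(nodes = nodes, free_nodes = free_nodes, fixed_nodes = fixed_nodes,
       fixed_vals = fixed_vals, inflow_node = inflow_node,
       wk3_nodes = wk3_nodes, n = n, nP = nP, nS = nS, nW = nW,
       qcol = qcol, ccol = ccol, from_free = from_free, to_free = to_free,
       from_fix = from_fix, to_fix = to_fix, seg = seg, Ldt = Ldt,
       wk_node_idx = wk_node_idx, Rp = Rp, Rd = Rd, Cdt = Cdt, Pref = Pref,
       inflow_row = inflow_row, M0 = M0)
}

#' @keywords internal
solver_residual <- function(sv, x, qprev, cprev, qin) {
  P <- x[seq_len(sv$nP)]
  Q <- x[sv$qcol]
  Pc <- if (sv$nW) x[sv$ccol] else numeric(0)
  pf <- ifelse(is.na(sv$from_free), sv$from_fix, P[sv$from_free])
  pt <- ifelse(is.na(sv$to_free), sv$to_fix, P[sv$to_free])
  r <- numeric(sv$n)
  # node balances
  bal <- numeric(sv$nP)
  for (j in seq_len(sv$nS)) {
    if (!is.na(sv$to_free[j]))   bal[sv$to_free[j]] <- bal[sv$to_free[j]] + Q[j]
    if (!is.na(sv$from_free[j])) bal[sv$from_free[j]] <- bal[sv$from_free[j]] - Q[j]
  }
  bal[sv$inflow_row] <- bal[sv$inflow_row] + qin
  if (sv$nW) {
    bal[sv$wk_node_idx] <- bal[sv$wk_node_idx] -
      (P[sv$wk_node_idx] - Pc) / sv$Rp
  }
  r[seq_len(sv$nP)] <- bal
  r[sv$nP + seq_len(sv$nS)] <- (pf - pt) - sv$seg$a * Q * abs(Q) -
    sv$seg$b * Q - sv$Ldt * (Q - qprev)
  if (sv$nW) {
    r[sv$ccol] <- sv$Cdt * (Pc - cprev) - (P[sv$wk_node_idx] - Pc) / sv$Rp +
      (Pc - sv$Pref) / sv$Rd
  }
  r
}

#' @keywords internal
solver_step <- function(sv, x, qprev, cprev, qin, qscale, pscale,
                        tol = 1e-10, maxit = 50L) {
  # row scales: balances & wk3 states ~ flow units, segment laws ~ pressure
  rsc <- c(rep(1 / qscale, sv$nP), rep(1 / pscale, sv$nS),
           rep(1 / qscale, sv$nW))
  csc <- c(rep(pscale, sv$nP), rep(qscale, sv$nS), rep(pscale, sv$nW))
  for (it in seq_len(maxit)) {
    r <- solver_residual(sv, x, qprev, cprev, qin)
    if (max(abs(r * rsc)) < tol) return(x)
    M <- sv$M0
    Q <- x[sv$qcol]
    diagq <- -(sv$seg$b + sv$Ldt + 2 * sv$seg$a * abs(Q))
    M[cbind(sv$nP + seq_len(sv$nS), sv$qcol)] <- diagq
    Ms <- M * rsc
    Ms <- sweep(Ms, 2L, csc, `*`)
    dx <- tryCatch(solve(Ms, -(r * rsc)), error = function(e) {
      stop("Newton step failed (singular 0D system): ", conditionMessage(e))
    })
    x <- x + dx * csc
  }
  stop("Newton iteration did not converge in the 0D time step")
}

#' Simulate a 0D network driven by a periodic inflow waveform
#'
#' Backward-Euler time integration with a full Newton solve per step. Each
#' step solves the coupled algebraic system of junction mass balances, segment
#' laws dP = a Q|Q| + b Q + L dQ/dt and Windkessel state laws. The simulation
#' runs up to `n_cycles` cardiac cycles and stops early once the per-cycle
#' peak inlet pressure satisfies the cyclic periodicity criterion (< 1%
#' change between subsequent cycles); the last simulated cycle is reported.
#'
#' @param net a [network0d()].
#' @param inflow a periodic [waveform()] in m^3/s, injected at the inflow node.
#' @param dt time step (s), default 1e-3.
#' @param n_cycles maximum number of cycles, default 8.
#' @param tol Newton tolerance (relative, on scaled residuals), default 1e-10.
#' @param min_cycles minimum cycles before the periodicity stop, default 2.
#' @param stop_when_periodic stop early when periodic, default TRUE.
#' @param init "steady" (default) starts from the steady state at the
#'   cycle-mean inflow, suppressing slow Windkessel charging transients;
#'   "zero" starts from rest (Q = 0, capacitors at their reference pressure),
#'   which exposes the physical step response.
#' @return object of class `network_solution`: `times` (last-cycle grid),
#'   `pressures` (time x node, Pa), `flows` (time x segment, m^3/s),
#'   `outlet_flows` (time x WK3 outlet), `outlet_fractions` (cycle-mean outlet
#'   flow / cycle-mean inflow), `systolic_inlet_pressure` (Pa),
#'   `peak_pressures` (per cycle), `converged_cycle`.
#' @export
simulate_network <- function(net, inflow, dt = 1e-3, n_cycles = 8L,
                             tol = 1e-10, min_cycles = 2L,
                             stop_when_periodic = TRUE,
                             init = c("steady", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(net, "network0d"), inherits(inflow, "waveform"))
  if (!inflow$periodic) stop("inflow waveform must be periodic")
  T_ <- inflow$period
  nsteps <- max(3L, floor(T_ / dt + 1e-9))
  tgrid <- (seq_len(nsteps) - 1) * dt
  qin_grid <- eval_waveform(inflow, tgrid)
  qscale <- max(abs(qin_grid), 1e-12)
  sv <- build_solver(net, dt)
  pscale <- qscale * max(c(sv$seg$b + 2 * sv$seg$a * qscale + sv$Ldt,
                           if (sv$nW) sv$Rp + sv$Rd else 1, 1))

  # initialise from the steady state at the cycle-mean inflow: Windkessel
  # compliances can carry time constants much longer than the cardiac period,
  # and a cold start would otherwise drift for many cycles
  cold <- function() {
    x0 <- numeric(sv$n)
    if (length(sv$fixed_vals)) x0[seq_len(sv$nP)] <- mean(sv$fixed_vals)
    if (sv$nW) x0[sv$ccol] <- sv$Pref
    x0
  }
  x <- if (init == "zero") {
    cold()
  } else {
    qmean <- mean(qin_grid)
    sv0 <- build_solver(net, dt = 1e12)
    tryCatch(
      solver_step(sv0, numeric(sv0$n), numeric(sv0$nS),
                  if (sv0$nW) sv0$Pref else numeric(0), qmean,
                  qscale, pscale, tol, maxit = 200L),
      error = function(e) cold())
  }
  qprev <- x[sv$qcol]
  cprev <- if (sv$nW) x[sv$ccol] else numeric(0)

  inlet_col <- match(sv$inflow_node, sv$free_nodes)
  peak_pressures <- numeric(0)
  converged <- NA_integer_
  P_hist <- matrix(0, nsteps, sv$nP)
  Q_hist <- matrix(0, nsteps, sv$nS)
  C_hist <- matrix(0, nsteps, max(sv$nW, 1L))

  for (cyc in seq_len(n_cycles)) {
    for (m in seq_len(nsteps)) {
      qin <- qin_grid[if (m == nsteps) 1L else m + 1L]  # value at t_{m}+dt
      x <- solver_step(sv, x, qprev, cprev, qin, qscale, pscale, tol)
      qprev <- x[sv$qcol]
      if (sv$nW) cprev <- x[sv$ccol]
      P_hist[m, ] <- x[seq_len(sv$nP)]
      Q_hist[m, ] <- x[sv$qcol]
      if (sv$nW) C_hist[m, ] <- x[sv$ccol]
    }
    peak_pressures <- c(peak_pressures, max(P_hist[, inlet_col]))
    if (length(peak_pressures) >= max(2L, min_cycles)) {
      k <- cyclic_periodicity_index(peak_pressures)
      if (!is.na(k)) {
        converged <- k
        if (stop_when_periodic) break
      }
    }
  }

  # assemble full node pressure matrix (free + fixed)
  pressures <- matrix(0, nsteps, length(sv$nodes),
                      dimnames = list(NULL, sv$nodes))
  pressures[, sv$free_nodes] <- P_hist
  for (i in seq_along(sv$fixed_nodes)) {
    pressures[, sv$fixed_nodes[i]] <- sv$fixed_vals[i]
  }
  colnames(Q_hist) <- sv$seg$name
  # WK3 outlet flows Q = (P_node - Pc)/Rp; grid shifted by dt (values at t+dt),
  # a uniform periodic grid so cycle means are plain sample means
  outlet_flows <- NULL
  outlet_fractions <- NULL
  if (sv$nW) {
    outlet_flows <- sapply(seq_len(sv$nW), function(w) {
      (P_hist[, sv$wk_node_idx[w]] - C_hist[, w]) / sv$Rp[w]
    })
    outlet_flows <- matrix(outlet_flows, nsteps, sv$nW,
                           dimnames = list(NULL, sv$wk3_nodes))
    qin_shift <- qin_grid[c(2:nsteps, 1L)]
    outlet_fractions <- colMeans(outlet_flows) / mean(qin_shift)
  }
  structure(list(times = tgrid + dt, dt = dt, period = T_,
                 pressures = pressures, flows = Q_hist,
                 outlet_flows = outlet_flows,
                 outlet_fractions = outlet_fractions,
                 inflow = qin_grid[c(2:nsteps, 1L)],
                 systolic_inlet_pressure = max(pressures[, sv$inflow_node]),
                 inflow_node = sv$inflow_node,
                 peak_pressures = peak_pressures,
                 converged_cycle = converged,
                 n_cycles_run = length(peak_pressures)),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf(paste0("network_solution: %d steps/cycle, %d cycle(s), ",
                     "systolic inlet pressure %.4g mmHg\n"),
              length(x$times), x$n_cycles_run,
              Pa_to_mmHg(x$systolic_inlet_pressure)))
  if (!is.null(x$outlet_fractions)) {
    cat("  outlet flow fractions:",
        paste(sprintf("%s=%.3f", names(x$outlet_fractions),
                      x$outlet_fractions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @keywords internal
steady_network_solve <- function(net, Q0, tol = 1e-10) {
  # steady state = one backward-Euler step with a huge dt from any state
  w <- waveform(c(0, 0.5, 1), rep(Q0, 3), period = 1, periodic = TRUE)
  sv <- build_solver(net, dt = 1e12)
  qscale <- max(abs(Q0), 1e-12)
  pscale <- qscale * max(c(sv$seg$b + 2 * sv$seg$a * qscale,
                           if (sv$nW) sv$Rp + sv$Rd else 1, 1))
  x <- numeric(sv$n)
  x <- solver_step(sv, x, numeric(sv$nS), if (sv$nW) sv$Pref else numeric(0),
                   Q0, qscale, pscale, tol, maxit = 200L)
  P <- stats::setNames(numeric(length(sv$nodes)), sv$nodes)
  P[sv$free_nodes] <- x[seq_len(sv$nP)]
  P[sv$fixed_nodes] <- sv$fixed_vals
  Q <- stats::setNames(x[sv$qcol], sv$seg$name)
  outlet <- if (sv$nW) {
    stats::setNames((x[sv$wk_node_idx] - x[sv$ccol]) / sv$Rp, sv$wk3_nodes)
  } else NULL
  list(pressures = P, flows = Q, outlet_flows = outlet)
}

#' Replace all WK3 terminations of a network with given parameters
#'
#' @param net a [network0d()].
#' @param params a [wk3_params()] applied identically at every WK3 outlet.
#' @return modified network.
#' @export
set_wk3 <- function(net, params) {
  stopifnot(inherits(net, "network0d"), inherits(params, "wk3_params"))
  for (nm in names(net$terminations)) {
    if (net$terminations[[nm]]$type == "wk3") net$terminations[[nm]] <- params
  }
  net
}

#' Calibrate identical WK3 outlet parameters against pressure and flow-split
#' targets
#'
#' Automates the usual manual tuning of outlet Windkessel parameters: the same
#' (R_p, R_d, C) triplet is applied at every WK3-terminated arterial outlet
#' and adjusted until the simulated systolic (peak) inlet pressure matches
#' `systolic_target` and the summed cycle-mean arterial outflow fraction of
#' the inlet flow matches `split_target` within `band`.
#'
#' The procedure is deterministic: a steady-state root finding on the total
#' outlet resistance (at the cycle-mean inflow, with the R_p:R_d ratio held at
#' its initial value) seeds a bounded Nelder-Mead minimisation over
#' log(R_p, R_d, C) of the weighted two-term relative objective
#' w_p ((P_sys - target)/target)^2 + w_s ((split - target)/target)^2.
#'
#' @param net a [network0d()] with at least one WK3 termination.
#' @param inflow periodic inflow [waveform()] (m^3/s).
#' @param systolic_target target systolic inlet pressure (Pa).
#' @param split_target target summed arterial outflow fraction (0..1).
#' @param band acceptable half-width on the achieved fraction, default 0.05.
#' @param P_ref distal reference pressure of the outlets (Pa), default 0.
#' @param ratio initial R_p/(R_p + R_d) ratio, default 0.4 (i.e. R_p:R_d =
#'   10:15, the classical proximal:distal proportion).
#' @param dt_calibrate time step used inside the optimisation (s).
#' @param dt_verify time step of the final verification run (s).
#' @param pressure_tol relative tolerance on the achieved systolic pressure,
#'   default 0.01.
#' @param weights length-2 weights (pressure, split) of the objective.
#' @param maxit Nelder-Mead iteration cap.
#' @return a [wk3_params()] with attributes `achieved` (systolic Pa, split)
#'   and `solution` (the verification [simulate_network()] run).
#' @export
calibrate_wk3 <- function(net, inflow, systolic_target, split_target,
                          band = 0.05, P_ref = 0, ratio = 0.4,
                          dt_calibrate = 2e-3, dt_verify = 1e-3,
                          pressure_tol = 0.01, weights = c(1, 1),
                          maxit = 200L) {
  stopifnot(inherits(net, "network0d"))
  n_wk3 <- sum(vapply(net$terminations, function(x) x$type, "") == "wk3")
  if (n_wk3 == 0L) stop("network has no WK3 terminations to calibrate")
  if (split_target <= 0 || split_target > 1) stop("split_target must be in (0, 1]")
  qmean <- waveform_mean(inflow)

  split_of <- function(log10_rtot) {
    rt <- 10^log10_rtot
    p <- wk3_params(ratio * rt, (1 - ratio) * rt, C = 1e-9, P_ref = P_ref)
    s <- steady_network_solve(set_wk3(net, p), qmean)
    sum(s$outlet_flows) / qmean
  }
  lo <- 5; hi <- 14
  s_lo <- split_of(lo)
  s_hi <- split_of(hi)
  if (split_target > s_lo + band) {
    stop(sprintf(paste0("infeasible split target %.3f: the venous path ",
                        "limits the achievable arterial fraction to %.3f ",
                        "even at near-zero outlet resistance"),
                 split_target, s_lo))
  }
  rtot0 <- if (split_target >= s_lo) {
    10^lo
  } else if (split_target <= s_hi) {
    10^hi
  } else {
    10^stats::uniroot(function(z) split_of(z) - split_target, c(lo, hi),
                      tol = 1e-6)$root
  }

  rd0 <- (1 - ratio) * rtot0
  c0 <- 1 / rd0                      # time constant R_d C ~ 1 s to start
  run <- function(theta, dt) {
    p <- wk3_params(exp(theta[1]), exp(theta[2]), exp(theta[3]), P_ref = P_ref)
    sol <- simulate_network(set_wk3(net, p), inflow, dt = dt)
    list(params = p, sol = sol,
         psys = sol$systolic_inlet_pressure,
         split = sum(sol$outlet_fractions))
  }
  objective <- function(theta) {
    r <- run(theta, dt_calibrate)
    weights[1] * ((r$psys - systolic_target) / systolic_target)^2 +
      weights[2] * ((r$split - split_target) / split_target)^2
  }
  theta0 <- log(c(ratio * rtot0, rd0, c0))
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  final <- run(opt$par, dt_verify)
  ok_p <- abs(final$psys - systolic_target) <= pressure_tol * systolic_target
  ok_s <- abs(final$split - split_target) <= band
  if (!ok_p || !ok_s) {
    stop(sprintf(paste0("calibration infeasible for the given targets: ",
                        "achieved systolic %.4g Pa (target %.4g), ",
                        "split %.4f (target %.4f +/- %.3f)"),
                 final$psys, systolic_target, final$split, split_target, band))
  }
  out <- final$params
  attr(out, "achieved") <- c(systolic_Pa = final$psys, split = final$split)
  attr(out, "solution") <- final$sol
  attr(out, "objective_value") <- opt$value
  out
}

#' Check junction mass conservation of a solution
#'
#' Recomputes, at every reported time and every non-terminated interior node,
#' the signed sum of segment flows; returns the maximum imbalance relative to
#' the peak inflow.
#'
#' @param net the simulated [network0d()].
#' @param sol the [simulate_network()] result.
#' @return maximum relative imbalance (dimensionless).
#' @export
mass_conservation_error <- function(net, sol) {
  seg <- net$segments
  types <- vapply(net$terminations, function(x) x$type, "")
  interior <- setdiff(net$nodes, names(net$terminations))
  qmax <- max(abs(sol$inflow))
  if (!length(interior)) return(0)
  worst <- 0
  for (nd in interior) {
    bal <- rep(0, nrow(sol$flows))
    for (j in seq_len(nrow(seg))) {
      if (seg$to[j] == nd) bal <- bal + sol$flows[, j]
      if (seg$from[j] == nd) bal <- bal - sol$flows[, j]
    }
    worst <- max(worst, max(abs(bal)) / qmax)
  }
  worst
}

#' Serialise / load a 0D network as YAML
#'
#' @param net a [network0d()].
#' @param path file path.
#' @return `network_to_yaml` returns `path` invisibly; `network_from_yaml`
#'   returns the [network0d()].
#' @export
network_to_yaml <- function(net, path) {
  stopifnot(inherits(net, "network0d"))
  terms <- lapply(net$terminations, function(tm) {
    if (inherits(tm, "wk3_params")) {
      list(type = "wk3", R_p = tm$R_p, R_d = tm$R_d, C = tm$C, P_ref = tm$P_ref)
    } else tm
  })
  obj <- list(nodes = as.list(net$nodes),
              segments = lapply(seq_len(nrow(net$segments)), function(i) {
                as.list(net$segments[i, , drop = FALSE])
              }),
              terminations = terms)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname network_to_yaml
#' @export
network_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(obj$segments, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  terms <- lapply(obj$terminations, function(tm) {
    switch(tm$type,
           wk3 = wk3_params(tm$R_p, tm$R_d, tm$C, tm$P_ref %||% 0),
           pressure = pressure_sink(tm$value),
           inflow = inflow_marker(),
           stop("unknown termination type: ", tm$type))
  })
  network0d(unlist(obj$nodes), seg, terms)
}

#' Write a network solution (last cycle) as CSV
#'
#' Columns: time, one pressure column per node (Pa), one flow column per
#' segment (m^3/s).
#'
#' @param sol a [simulate_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(sol, path) {
  df <- data.frame(time_s = sol$times, check.names = FALSE)
  for (nm in colnames(sol$pressures)) df[[paste0("P_", nm)]] <- sol$pressures[, nm]
  for (nm in colnames(sol$flows))     df[[paste0("Q_", nm)]] <- sol$flows[, nm]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
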