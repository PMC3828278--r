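#' Fixture: irreversible linear chain with closed-form steady state
#'
#' `X0 -> S1 -> ... -> S_{n-1} -> (sink)` with mass-action rates
#' `v_i = k_i * S_{i-1}` and `X0` held constant (boundary). The chain has a
#' closed-form steady state: flux `J = k1 * X0`, concentrations
#' `S_i = k1 * X0 / k_{i+1}`. All flux control sits on the first step, so
#' the model exercises the whole pipeline against exactly known values.
#'
#' @param n number of reaction steps (>= 2).
#' @param k positive rate constants, length `n`.
#' @param x0 boundary substrate concentration.
#' @return list with elements `model` (a [kinetic_model()]) and `oracle`
#'   (closed-form steady state, fluxes and control coefficients).
#' @export
make_irreversible_chain <- function(n = 2, k = NULL, x0 = 1) {
  if (n < 2) stop("chain needs n >= 2 steps")
  if (is.null(k)) k <- seq(2, length.out = n)
  stopifnot(length(k) == n)
  if (any(k <= 0)) stop("rate constants must be positive")
  kid <- paste0("k", seq_len(n))
  sid <- paste0("S", seq_len(n - 1))
  species <- data.frame(
    id = c("X0", sid),
    initial = c(x0, rep(0, n - 1)),
    boundary = c(TRUE, rep(FALSE, n - 1))
  )
  rx <- vector("list", n)
  for (i in seq_len(n)) {
    from <- if (i == 1) "X0" else sid[i - 1]
    st <- c(-1)
    names(st) <- from
    if (i < n) st[sid[i]] <- 1
    rx[[i]] <- reaction(paste0("step", i), st, paste0(kid[i], "*", from))
  }
  params <- data.frame(id = kid, value = k, role = "limiting-rate")
  model <- kinetic_model(species, rx, params, id = "irreversible_chain")

  oracle <- list(
    flux = function(p = reference_params(model)) unname(p["k1"]) * x0,
    concentrations = function(p = reference_params(model)) {
      setNames(unname(p["k1"]) * x0 / p[kid[-1]], sid)
    },
    # flux control: step 1 carries it all; concentration control of S_i:
    # +1 on the producing chain entry, -1 on its consuming step
    fcc = function() setNames(c(1, rep(0, n - 1)), paste0("step", seq_len(n))),
    ccc = function() {
      m <- matrix(0, n - 1, n,
                  dimnames = list(sid, paste0("step", seq_len(n))))
      for (i in seq_len(n - 1)) {
        m[i, 1] <- 1
        m[i, i + 1] <- -1
      }
      m
    },
    # scaled response of flux / concentrations to the rate constants
    flux_response = function() setNames(c(1, rep(0, n - 1)), kid),
    conc_response = function(i) {
      r <- setNames(rep(0, n), kid)
      r["k1"] <- 1
      r[kid[i + 1]] <- -1
      r
    }
  )
  list(model = model, oracle = oracle)
}

# Assemble the steady-state linear system A s = b of the reversible chain
# (internal species only), plus exact derivative structures with respect
# to a rate constant or a reaction multiplier. Used by the fixture oracle
# -- an analytic route entirely independent of the ODE/Newton/finite-
# difference machinery under test.
rev_chain_system <- function(kf, kr, f, x0, x1) {
  n <- length(kf)
  m <- n - 1
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    A[i, i] <- -(f[i] * kr[i] + f[i + 1] * kf[i + 1])
    if (i > 1) A[i, i - 1] <- f[i] * kf[i]
    if (i < m) A[i, i + 1] <- f[i + 1] * kr[i + 1]
  }
  b[1] <- b[1] - f[1] * kf[1] * x0
  b[m] <- b[m] - f[n] * kr[n] * x1
  list(A = A, b = b, n = n, m = m)
}

rev_chain_deriv <- function(sys, kf, kr, f, x0, x1, type, j) {
  # dA/dtheta and db/dtheta for theta in {kf_j, kr_j, f_j}
  m <- sys$m; n <- sys$n
  dA <- matrix(0, m, m)
  db <- numeric(m)
  add_kf <- function(w) {
    if (j >= 2 && j <= m) dA[j, j - 1] <<- dA[j, j - 1] + w * f[j]
    if (j - 1 >= 1 && j - 1 <= m) dA[j - 1, j - 1] <<- dA[j - 1, j - 1] - w * f[j]
    if (j == 1) db[1] <<- db[1] - w * f[1] * x0
  }
  add_kr <- function(w) {
    if (j <= m) dA[j, j] <<- dA[j, j] - w * f[j]
    if (j - 1 >= 1 && j <= m) dA[j - 1, j] <<- dA[j - 1, j] + w * f[j]
    if (j == n) db[m] <<- db[m] - w * f[n] * x1
  }
  if (type == "kf") add_kf(1)
  else if (type == "kr") add_kr(1)
  else { # multiplier f_j scales both kf_j and kr_j terms
    add_kf(kf[j] / f[j])
    add_kr(kr[j] / f[j])
  }
  list(dA = dA, db = db)
}

#' Fixture: reversible first-order chain between two boundary pools
#'
#' `X0 <-> S1 <-> ... <-> S_{n-1} <-> X1` with rates
#' `v_i = kf_i * S_{i-1} - kr_i * S_i` and both end pools fixed. The steady
#' state is the solution of a linear system, so the oracle computes exact
#' steady states, fluxes, control coefficients and response coefficients
#' by linear algebra (implicit differentiation of `A s = b`) -- a route
#' independent of the finite-difference pipeline.
#'
#' @param n number of reversible steps (>= 2).
#' @param kf,kr positive forward / reverse rate constants, length `n`.
#' @param x0,x1 boundary pool concentrations.
#' @return list with elements `model` and `oracle`. The oracle exposes
#'   `steady_state(p)`, `control(p)` (flux-control vector and
#'   concentration-control matrix at the reference multipliers), and
#'   `response(p, target, parameter)` for scaled response coefficients of
#'   the flux (`target = "flux"`) or a species concentration to any rate
#'   constant.
#' @export
make_reversible_chain <- function(n = 2, kf = NULL, kr = NULL,
                                  x0 = 1, x1 = 0) {
  if (n < 2) stop("chain needs n >= 2 steps")
  if (is.null(kf)) kf <- rep(2, n)
  if (is.null(kr)) kr <- rep(1, n)
  stopifnot(length(kf) == n, length(kr) == n)
  if (any(c(kf, kr) <= 0)) stop("rate constants must be positive")
  sid <- paste0("S", seq_len(n - 1))
  nodes <- c("X0", sid, "X1")
  species <- data.frame(
    id = nodes,
    initial = c(x0, rep(0, n - 1), x1),
    boundary = c(TRUE, rep(FALSE, n - 1), TRUE)
  )
  rx <- vector("list", n)
  for (i in seq_len(n)) {
    st <- c(-1, 1)
    names(st) <- nodes[c(i, i + 1)]
    rx[[i]] <- reaction(
      paste0("step", i), st,
      paste0("kf", i, "*", nodes[i], " - kr", i, "*", nodes[i + 1]))
  }
  params <- data.frame(
    id = c(paste0("kf", seq_len(n)), paste0("kr", seq_len(n))),
    value = c(kf, kr), role = "other")
  model <- kinetic_model(species, rx, params, id = "reversible_chain")

  get_k <- function(p) list(kf = unname(p[paste0("kf", seq_len(n))]),
                            kr = unname(p[paste0("kr", seq_len(n))]))

  solve_ss <- function(kf, kr, f = rep(1, n)) {
    sys <- rev_chain_system(kf, kr, f, x0, x1)
    s <- tryCatch(solve(sys$A, sys$b),
                  error = function(e) stop("singular steady-state system: ",
                                           conditionMessage(e)))
    J <- f[n] * (kf[n] * s[sys$m] - kr[n] * x1)
    list(s = setNames(s, sid), J = J, sys = sys)
  }

  dtheta <- function(kf, kr, f, ss, type, j) {
    d <- rev_chain_deriv(ss$sys, kf, kr, f, x0, x1, type, j)
    ds <- solve(ss$sys$A, d$db - d$dA %*% unname(ss$s))
    explicit <- 0
    if (j == n) {
      explicit <- switch(type,
        f = ss$J / f[n],
        kf = f[n] * unname(ss$s[ss$sys$m]),
        kr = -f[n] * x1)
    }
    dJ <- explicit + f[n] * kf[n] * ds[ss$sys$m]
    list(ds = as.vector(ds), dJ = dJ)
  }

  oracle <- list(
    steady_state = function(p = reference_params(model)) {
      k <- get_k(p)
      ss <- solve_ss(k$kf, k$kr)
      list(concentrations = ss$s, flux = ss$J)
    },
    control = function(p = reference_params(model)) {
      k <- get_k(p)
      f <- rep(1, n)
      ss <- solve_ss(k$kf, k$kr, f)
      fcc <- numeric(n)
      ccc <- matrix(0, n - 1, n,
                    dimnames = list(sid, paste0("step", seq_len(n))))
      for (j in seq_len(n)) {
        d <- dtheta(k$kf, k$kr, f, ss, "f", j)
        fcc[j] <- f[j] / ss$J * d$dJ
        ccc[, j] <- f[j] / unname(ss$s) * d$ds
      }
      list(fcc = setNames(fcc, paste0("step", seq_len(n))), ccc = ccc)
    },
    response = function(p, target, parameter) {
      k <- get_k(p)
      f <- rep(1, n)
      ss <- solve_ss(k$kf, k$kr, f)
      type <- substr(parameter, 1, 2)
      j <- as.integer(substring(parameter, 3))
      th <- unname(p[parameter])
      d <- dtheta(k$kf, k$kr, f, ss, type, j)
      if (identical(target, "flux")) th / ss$J * d$dJ
      else th / unname(ss$s[target]) * d$ds[match(target, sid)]
    }
  )
  list(model = model, oracle = oracle)
}

#' Fixture: harmonic oscillator in rate-rule form
#'
#' `du/dt = omega * v`, `dv/dt = -omega * u`, `u(0) = 1`, `v(0) = 0`: a
#' pure centre with period exactly `2 * pi / omega`. Written as explicit
#' rate rules (no reactions), so it exercises the raw-ODE code path and
#' the event-free oscillation-period detector. The scaled sensitivity of
#' the period to `omega` is exactly -1.
#'
#' @param omega angular frequency (> 0), exposed as a model parameter.
#' @return list with elements `model` and `oracle` (`period`,
#'   `period_sensitivity`).
#' @export
make_linear_oscillator <- function(omega = pi) {
  if (omega <= 0) stop("omega must be positive")
  model <- kinetic_model(
    species = data.frame(id = c("u", "v"), initial = c(1, 0)),
    reactions = list(),
    parameters = data.frame(id = "omega", value = omega, role = "other"),
    rate_rules = list(u = "omega*v", v = "-omega*u"),
    id = "linear_oscillator")
  oracle <- list(
    period = function(p = reference_params(model)) 2 * pi / unname(p["omega"]),
    period_sensitivity = function() -1
  )
  list(model = model, oracle = oracle)
}

#' Fixture: branch-point pathway with a switching control pattern
#'
#' A constant supply `v0 = V0 * X0` feeds a metabolite `S` drained by two
#' saturable branches `v1 = V1 * S / (K1 + S)` and
#' `v2 = V2 * S / (K2 + S)`. Which branch operates near saturation depends
#' on the relative capacities, and with it the flux-control coefficient of
#' branch 1 on its own flux switches between ~0 (branch 1 far from
#' saturation, flux pinned by the supply/other branch) and ~1 (branch 1
#' saturated, its limiting rate controls its flux). Closed form at the
#' steady state: `C = a2 / (a1 + a2)` with
#' `a_i = V_i * K_i / (K_i + S)^2`.
#'
#' At the reference parameter values branch 1 has spare capacity, so `C`
#' is small; wide uniform sampling of the parameters crosses the
#' saturation switch and the control distribution becomes bimodal -- the
#' fixture used to exercise the pattern-of-control classifier.
#'
#' @param V0,V1,K1,V2,K2 reference parameter values.
#' @return list with elements `model` and `oracle` (`steady_state(p)` by
#'   1-D root finding and `control_b1_V1(p)` from the closed form above).
#' @export
make_bimodal_control_toy <- function(V0 = 1, V1 = 2, K1 = 0.02,
                                     V2 = 1.5, K2 = 1) {
  species <- data.frame(id = c("X0", "S"), initial = c(1, 0.02),
                        boundary = c(TRUE, FALSE))
  rx <- list(
    reaction("supply", c(S = 1), "V0*X0"),
    reaction("branch1", c(S = -1), "V1*S/(K1+S)"),
    reaction("branch2", c(S = -1), "V2*S/(K2+S)")
  )
  params <- data.frame(id = c("V0", "V1", "K1", "V2", "K2"),
                       value = c(V0, V1, K1, V2, K2),
                       role = c("limiting-rate", "limiting-rate", "other",
                                "limiting-rate", "other"))
  model <- kinetic_model(species, rx, params, id = "bimodal_control_toy")

  toy_ss <- function(p) {
    p <- as.list(p)
    drain <- function(s) p$V1 * s / (p$K1 + s) + p$V2 * s / (p$K2 + s)
    vin <- p$V0 * 1
    if (vin >= p$V1 + p$V2) return(NULL) # branches cannot absorb the supply
    hi <- max(p$K1, p$K2)
    while (drain(hi) < vin) hi <- hi * 2
    stats::uniroot(function(s) drain(s) - vin, c(0, hi),
                   tol = .Machine$double.eps^0.75)$root
  }
  oracle <- list(
    steady_state = toy_ss,
    control_b1_V1 = function(p = reference_params(model)) {
      s <- toy_ss(p)
      if (is.null(s)) return(NA_real_)
      p <- as.list(p)
      a1 <- p$V1 * p$K1 / (p$K1 + s)^2
      a2 <- p$V2 * p$K2 / (p$K2 + s)^2
      a2 / (a1 + a2)
    }
  )
  list(model = model, oracle = oracle)
}

#' Materialise a named fixture model
#'
#' @param name one of `"chain"`, `"reversible_chain"`, `"oscillator"`,
#'   `"bimodal_toy"`.
#' @param ... passed to the underlying `make_*` generator.
#' @return list with elements `model` and `oracle`.
#' @export
fixture <- function(name = c("chain", "reversible_chain", "oscillator",
                             "bimodal_toy"), ...) {
  name <- match.arg(name)
  switch(name,
    chain = make_irreversible_chain(...),
    reversible_chain = make_reversible_chain(...),
    oscillator = make_linear_oscillator(...),
    bimodal_toy = make_bimodal_control_toy(...))
}

#' Read a model back from its JSON summary
#'
#' Inverse of [model_summary_json()]: reconstructs a [kinetic_model()]
#' from the exported JSON so that fixtures can be materialised to disk and
#' reloaded with identical right-hand sides.
#'
#' @param path path to a JSON file written by [model_summary_json()], or a
#'   JSON string.
#' @return a `kinetic_model`.
#' @export
model_from_json <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_df <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rx <- lapply(s$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, r$rate)
  })
  rules <- if (length(s$rate_rules)) lapply(s$rate_rules, identity) else NULL
  kinetic_model(species = as_df(s$species), reactions = rx,
                parameters = as_df(s$parameters),
                compartments = as_df(s$compartments),
                rate_rules = rules, id = s$id)
}
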