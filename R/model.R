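## Internal model compilation: a validated configuration is flattened into a
## "plan" of dense arrays shared by the R reference engine and the compiled
## core.  All masses inside a plan are normalized by the configuration's
## reference mass, so the dynamical equations apply literally; simulate()
## rescales outputs back.

compile_plan <- function(cfg) {
  validate_config(cfg)
  g <- polymer_grid(cfg$grid$p_min, cfg$grid$p_max, cfg$grid$dp,
                    cfg$grid$uptake_frac)
  n <- g$n
  cls <- names(cfg$classes)
  mic <- names(cfg$communities)
  enz <- names(cfg$enzymes)
  nc <- length(cls); nm <- length(mic); ne <- length(enz)
  ref <- cfg$reference_mass

  prof <- function(mass, cl) {
    gaussian_profile(g, mass, cl$center_frac, cl$sd_frac)$density
  }
  chi_ac <- sapply(cfg$classes, function(cl) prof(cl$accessible / ref, cl))
  chi_in <- sapply(cfg$classes, function(cl) prof(cl$inaccessible / ref, cl))
  inp_ac <- sapply(cfg$classes, function(cl) prof(cl$input_accessible / ref, cl))
  inp_in <- sapply(cfg$classes, function(cl) prof(cl$input_inaccessible / ref, cl))
  dim(chi_ac) <- dim(chi_in) <- dim(inp_ac) <- dim(inp_in) <- c(n, nc)

  K <- lapply(cfg$enzymes, function(e) unclass(cleavage_operator(g, e$alpha)))
  enz_target <- vapply(cfg$enzymes, function(e) match(e$target, cls), 1L)
  enz_tau0 <- vapply(cfg$enzymes, `[[`, 0, "tau0")
  W <- matrix(0, ne, nm, dimnames = list(enz, mic))
  for (e in seq_len(ne)) {
    pr <- cfg$enzymes[[e]]$producers
    W[e, names(pr)] <- pr
  }

  named_per_class <- function(v, default = 0) {
    out <- rep(default, nc)
    names(out) <- cls
    if (length(v) == 1 && is.null(names(v))) out[] <- v else out[names(v)] <- v
    out
  }
  u0 <- t(sapply(cfg$communities, function(m) named_per_class(m$u0)))
  e0 <- t(sapply(cfg$communities, function(m) named_per_class(m$e0)))
  m0 <- vapply(cfg$communities, `[[`, 0, "m0")
  dim(u0) <- dim(e0) <- c(nm, nc)

  sig_shape <- prof(1, cfg$classes[[1]])  # unit-mass necromass profile
  sig <- lapply(cfg$communities, function(m) {
    s <- matrix(0, n, nc)
    fr <- named_per_class(m$signature)
    for (c in seq_len(nc)) s[, c] <- sig_shape * fr[c]
    s
  })
  resid_frac <- vapply(cfg$communities,
                       function(m) 1 - sum(m$signature), 0)

  tau_ac <- numeric(nc); tau_in <- numeric(nc); gates <- list()
  for (c in seq_len(nc)) {
    ta <- cfg$classes[[c]]$to_accessible
    if (inherits(ta, "cs_gate")) {
      gates[[length(gates) + 1]] <- list(
        target = c, enzyme = match(ta$enzyme, enz), coef = ta$coef)
    } else {
      tau_ac[c] <- ta
    }
    tau_in[c] <- cfg$classes[[c]]$to_inaccessible
  }

  biomass <- vapply(cfg$communities, `[[`, 0, "biomass") / ref

  list(grid = g, n = n, dp = g$dp, du = g$in_uptake,
       n_class = nc, n_mic = nm, n_enz = ne,
       class_names = cls, mic_names = mic, enz_names = enz,
       K = K, enz_target = enz_target, enz_tau0 = enz_tau0, W = W,
       u0 = u0, e0 = e0, m0 = m0, sig = sig, resid_frac = resid_frac,
       tau_ac = tau_ac, tau_in = tau_in, gates = gates,
       inp_ac = inp_ac, inp_in = inp_in,
       state0 = pack_state(chi_ac, chi_in, biomass, 0, numeric(nm)),
       ref = ref)
}

pack_state <- function(chi_ac, chi_in, biomass, co2, residues) {
  c(rbind(chi_ac, chi_in), biomass, co2, residues)
}

unpack_state <- function(y, plan) {
  n <- plan$n; nc <- plan$n_class; nm <- plan$n_mic
  blk <- matrix(y[seq_len(2 * n * nc)], nrow = 2 * n)
  list(chi_ac = blk[seq_len(n), , drop = FALSE],
       chi_in = blk[n + seq_len(n), , drop = FALSE],
       biomass = y[2 * n * nc + seq_len(nm)],
       co2 = y[2 * n * nc + nm + 1],
       residues = y[2 * n * nc + nm + 1 + seq_len(nm)])
}

## Reference derivative of the full state (normalized units).  This is the
## method-of-lines right-hand side assembled in plain R; the compiled core
## implements the same assembly and is cross-checked against this in tests.
cs_deriv <- function(y, plan) {
  s <- unpack_state(y, plan)
  chi_ac <- s$chi_ac; chi_in <- s$chi_in; B <- s$biomass
  n <- plan$n; nc <- plan$n_class; nm <- plan$n_mic
  dp <- plan$dp; du <- plan$du

  taus <- plan$enz_tau0 * as.vector(plan$W %*% B)        # realized rates, 1/d
  tau_ac <- plan$tau_ac
  for (gt in plan$gates) {
    src <- plan$enz_target[gt$enzyme]
    tau_ac[gt$target] <- tau_ac[gt$target] +
      gt$coef * taus[gt$enzyme] * sum(chi_ac[, src]) * dp
  }

  U <- colSums(chi_ac[du, , drop = FALSE]) * dp          # uptake-available C
  upt_rate <- as.vector(t(plan$u0) %*% B)                # per class, 1/d

  d_ac <- matrix(0, n, nc); d_in <- matrix(0, n, nc)
  for (c in seq_len(nc)) {
    d_ac[, c] <- tau_ac[c] * chi_in[, c] - plan$tau_in[c] * chi_ac[, c] +
      plan$inp_ac[, c]
    d_in[, c] <- plan$tau_in[c] * chi_ac[, c] - tau_ac[c] * chi_in[, c] +
      plan$inp_in[, c]
    d_ac[du, c] <- d_ac[du, c] - upt_rate[c] * chi_ac[du, c]
  }
  for (e in seq_len(plan$n_enz)) {
    if (taus[e] == 0) next
    tg <- plan$enz_target[e]
    d_ac[, tg] <- d_ac[, tg] +
      taus[e] * (plan$K[[e]] %*% chi_ac[, tg] - chi_ac[, tg])
  }
  for (m in seq_len(nm)) {
    d_ac <- d_ac + plan$m0[m] * B[m] * plan$sig[[m]]
  }

  assim <- rowSums(plan$u0 * plan$e0 * rep(U, each = nm))   # per community
  dB <- -plan$m0 * B + B * assim
  dco2 <- sum(B * rowSums(plan$u0 * (1 - plan$e0) * rep(U, each = nm)))
  dres <- plan$m0 * B * plan$resid_frac
  pack_state(d_ac, d_in, dB, dco2, dres)
}

## Largest biomass-driven decay rate in the system; bounds the stable
## explicit step (used for internal sub-stepping).
cs_stiffness <- function(y, plan) {
  s <- unpack_state(y, plan)
  B <- s$biomass; dp <- plan$dp
  taus <- plan$enz_tau0 * as.vector(plan$W %*% B)
  lam_cls <- rep(0, plan$n_class)
  for (e in seq_len(plan$n_enz)) {
    lam_cls[plan$enz_target[e]] <- lam_cls[plan$enz_target[e]] + taus[e]
  }
  lam_cls <- lam_cls + as.vector(t(plan$u0) %*% B) + plan$tau_in
  lam_tr <- plan$tau_ac
  for (gt in plan$gates) {
    src <- plan$enz_target[gt$enzyme]
    lam_tr[gt$target] <- lam_tr[gt$target] +
      gt$coef * taus[gt$enzyme] * sum(s$chi_ac[, src]) * dp
  }
  max(lam_cls, lam_tr, plan$m0)
}

## ---- exported flux operations -------------------------------------------

#' Microbial uptake flux
#'
#' Removal rate of accessible carbon by one community: proportional to its
#' biomass and to the density, and restricted to the uptake domain
#' \eqn{D_u}.  The integral of the returned flux equals
#' `u0 * biomass * uptake_carbon(dist)`.
#'
#' @param dist accessible-pool [polymer_distribution()].
#' @param u0 uptake rate (1/(g_C d)) of the community on this class.
#' @param biomass community biomass carbon (g_C).
#' @return flux density (g_C / p / d) at bin centers, positive on `D_u`,
#'   zero elsewhere; to be subtracted from the pool.
#' @export
uptake_flux <- function(dist, u0, biomass) {
  stopifnot(inherits(dist, "polymer_distribution"), u0 >= 0, biomass >= 0)
  out <- numeric(dist$grid$n)
  du <- dist$grid$in_uptake
  out[du] <- u0 * biomass * dist$density[du]
  out
}

#' Necromass return flux
#'
#' Rate at which dead biomass of a community is deposited into the
#' accessible pool of one class: `m0 * biomass * signature_fraction`,
#' spread over the standard necromass profile.  Summed over classes the
#' deposited carbon rate is `m0 * biomass * sum(signature)`.
#'
#' @param grid the class's [polymer_grid()].
#' @param community a [microbial_community()].
#' @param class_name which class's share of the signature to return.
#' @param biomass optional biomass override (defaults to the community's).
#' @return flux density (g_C / p / d) at bin centers.
#' @export
necromass_flux <- function(grid, community, class_name,
                           biomass = community$biomass) {
  stopifnot(inherits(community, "cs_community"))
  frac <- community$signature[class_name]
  if (is.na(frac)) frac <- 0
  rate <- community$m0 * biomass * frac
  if (rate == 0) return(rep(0, grid$n))
  gaussian_profile(grid, rate)$density
}

#' Accessibility transfer fluxes
#'
#' Exchange between the enzyme-inaccessible and accessible pools of one
#' class.  The polymerization shape is preserved exactly: the flux toward
#' accessibility is `to_accessible * chi_in(p)` and the reverse
#' `to_inaccessible * chi_ac(p)`, so the class's total carbon is conserved
#' by this pair of terms.
#'
#' @param accessible,inaccessible the two [polymer_distribution()]s.
#' @param to_accessible,to_inaccessible transfer rates (1/d).
#' @return list with flux densities `to_ac` (into the accessible pool) and
#'   `to_in` (into the inaccessible pool), both g_C / p / d.
#' @export
accessibility_fluxes <- function(accessible, inaccessible,
                                 to_accessible, to_inaccessible) {
  stopifnot(to_accessible >= 0, to_inaccessible >= 0)
  list(to_ac = to_accessible * inaccessible$density,
       to_in = to_inaccessible * accessible$density)
}

#' Full state derivative
#'
#' Assembles the instantaneous rate of change of every pool, biomass, the
#' CO2 efflux and the untracked-residue rate for a configuration and state:
#' accessibility transfers, enzymatic depolymerization, necromass return,
#' microbial uptake and external input for each class; biomass balance
#' (mortality vs. assimilated uptake) per community.  Units follow the
#' configuration (g_C, d).
#'
#' @param cfg a [cstability_config()].
#' @param state optional list with `chi_ac`, `chi_in` (density matrices,
#'   bins x classes), `biomass` (per community); defaults to the
#'   configuration's initial state.
#' @return list with `chi_ac`, `chi_in` (matrices of density rates),
#'   `biomass` (per community), `co2` and `residues` rates.
#' @export
state_derivative <- function(cfg, state = NULL) {
  plan <- compile_plan(cfg)
  y <- plan$state0
  if (!is.null(state)) {
    y <- pack_state(state$chi_ac / plan$ref, state$chi_in / plan$ref,
                    state$biomass / plan$ref, 0, numeric(plan$n_mic))
  }
  if (any(!is.finite(y)) || any(unpack_state(y, plan)$biomass < 0)) {
    stop("invalid state: non-finite values or negative biomass", call. = FALSE)
  }
  d <- unpack_state(cs_deriv(y, plan), plan)
  d <- lapply(d, `*`, plan$ref)
  d$biomass <- stats::setNames(d$biomass, plan$mic_names)
  d$residues <- stats::setNames(d$residues, plan$mic_names)
  d$co2 <- unname(d$co2)
  d
}

#' CO2 efflux of a state
#'
#' Respiration rate: the non-assimilated share of microbial uptake,
#' \eqn{\sum_{mic} C_{mic} \sum_* u^0 (1 - e^0) \int_{D_u} \chi^{ac}_* dp}.
#'
#' @inheritParams state_derivative
#' @return CO2 production rate (g_C/d).
#' @export
co2_flux <- function(cfg, state = NULL) {
  state_derivative(cfg, state)$co2
}
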