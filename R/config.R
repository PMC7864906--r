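#' Substrate class specification
#'
#' Describes one biochemical class (e.g. cellulose, lignin, lipid, protein,
#' microbial sugar): its initial carbon in the enzyme-accessible and
#' enzyme-inaccessible pools, any constant input flux, and the transfer
#' rates between the two pools.  Initial pools and inputs use the standard
#' truncated-Gaussian profile of [gaussian_profile()].
#'
#' @param name class name, unique within a configuration.
#' @param accessible,inaccessible initial carbon mass (g_C) in each pool.
#' @param input_accessible,input_inaccessible constant input rate
#'   (g_C/d) deposited with the standard profile into each pool.
#' @param to_accessible transfer rate (1/d) from inaccessible to accessible,
#'   or a [gated_transfer()] tying the rate to an enzyme family's activity.
#' @param to_inaccessible transfer rate (1/d) in the opposite direction.
#' @param center_frac,sd_frac profile shape parameters, see
#'   [gaussian_profile()].
#' @return a list of class `cs_class`.
#' @export
substrate_class <- function(name, accessible = 0, inaccessible = 0,
                            input_accessible = 0, input_inaccessible = 0,
                            to_accessible = 0, to_inaccessible = 0,
                            center_frac = 0.25, sd_frac = 0.05) {
  stopifnot(is.character(name), accessible >= 0, inaccessible >= 0,
            input_accessible >= 0, input_inaccessible >= 0,
            to_inaccessible >= 0)
  if (!inherits(to_accessible, "cs_gate")) stopifnot(to_accessible >= 0)
  structure(
    list(name = name, accessible = accessible, inaccessible = inaccessible,
         input_accessible = input_accessible,
         input_inaccessible = input_inaccessible,
         to_accessible = to_accessible, to_inaccessible = to_inaccessible,
         center_frac = center_frac, sd_frac = sd_frac),
    class = "cs_class"
  )
}

#' Enzyme-gated accessibility transfer
#'
#' Ties the inaccessible-to-accessible transfer rate of a class to the
#' realized activity of an enzyme family on its own substrate:
#' \deqn{\tau_{tr}^{ac}(t) = c \, \tau^0_{enz} C_{mic}(t)
#'   \int_{D_{enz}} \chi^{ac}_{target}(p, t)\, dp,}
#' the mechanism by which, e.g., lignin depolymerization progressively
#' exposes cellulose embedded in lignocellulose.
#'
#' @param coef coupling coefficient (1/g_C).
#' @param enzyme name of the gating enzyme family.
#' @return a list of class `cs_gate`.
#' @export
gated_transfer <- function(coef, enzyme) {
  stopifnot(coef >= 0, is.character(enzyme))
  structure(list(coef = coef, enzyme = enzyme), class = "cs_gate")
}

#' Microbial community specification
#'
#' A functional community with biomass-proportional traits: per-class uptake
#' rates `u0`, carbon use efficiencies `e0` (fraction of taken-up carbon
#' assimilated; the rest is respired as CO2), mortality rate `m0`, and a
#' necromass signature: the biochemical composition of dead biomass returned
#' to the accessible substrate pools.  Signature fractions may sum to less
#' than one; the remainder accumulates as untracked microbial residue
#' (no recycling), which the simulator still books for mass balance.
#'
#' @param name community name.
#' @param biomass initial biomass carbon (g_C).
#' @param e0 carbon use efficiency in `[0, 1]`; scalar or named per class.
#' @param m0 mortality rate (1/d).
#' @param u0 named numeric: uptake rate (1/(g_C d)) per class; classes
#'   absent from the vector get 0.
#' @param signature named numeric: necromass mass fractions per class,
#'   summing to at most 1.
#' @return a list of class `cs_community`.
#' @export
microbial_community <- function(name, biomass, e0, m0, u0,
                                signature = numeric()) {
  stopifnot(is.character(name), biomass >= 0, all(e0 >= 0), all(e0 <= 1),
            m0 >= 0, all(u0 >= 0), all(signature >= 0))
  if (sum(signature) > 1 + 1e-9) {
    stop("signature fractions must sum to at most 1", call. = FALSE)
  }
  structure(
    list(name = name, biomass = biomass, e0 = e0, m0 = m0,
         u0 = u0, signature = signature),
    class = "cs_community"
  )
}

#' Enzyme family specification
#'
#' @param name family name (e.g. "cellulolysis").
#' @param target name of the substrate class it depolymerizes.
#' @param tau0 action rate per unit microbial carbon (1/(g_C d)).
#' @param alpha cleavage factor, >= 0 (low: endo-cleaving, high:
#'   exo-cleaving), see [kernel_density()].
#' @param producers named numeric: weight per producing community (usually 1).
#' @return a list of class `cs_enzyme`.
#' @export
enzyme_family <- function(name, target, tau0, alpha, producers) {
  stopifnot(is.character(name), is.character(target), tau0 >= 0, alpha >= 0,
            length(producers) >= 1, all(producers >= 0))
  structure(
    list(name = name, target = target, tau0 = tau0, alpha = alpha,
         producers = producers),
    class = "cs_enzyme"
  )
}

#' Model configuration
#'
#' Assembles classes, communities and enzyme families into a validated,
#' simulation-ready configuration.
#'
#' `reference_mass` sets the carbon mass (g_C) against which the
#' biomass-proportional rate coefficients (`tau0`, `u0`, gate coefficients)
#' are expressed: the realized rates are, e.g.,
#' \eqn{\tau = \tau^0 C_{mic} / C_{ref}}.  The batch scenarios state their
#' initial amounts per 100 g_C of system carbon, so their builders use
#' `reference_mass = 100`; the steady-state scenario works in absolute areal
#' densities (g_C/cm2) and uses `reference_mass = 1`.
#'
#' @param classes list of [substrate_class()] objects.
#' @param communities list of [microbial_community()] objects.
#' @param enzymes list of [enzyme_family()] objects.
#' @param reference_mass reference carbon mass (g_C), see Details.
#' @param grid list with `p_min`, `p_max`, `dp`, `uptake_frac` applied to
#'   every class.
#' @param solver list with time step `dt` (d), horizon `t_end` (d), output
#'   cadence `output_every` (d).
#' @param name configuration label.
#' @return an object of class `cstability_config`.
#' @export
cstability_config <- function(classes, communities, enzymes,
                              reference_mass = 1,
                              grid = list(p_min = 0, p_max = 2, dp = 0.01,
                                          uptake_frac = 0.2),
                              solver = list(dt = 0.1, t_end = 365,
                                            output_every = 1),
                              name = "custom") {
  cfg <- structure(
    list(name = name,
         classes = stats::setNames(classes, vapply(classes, `[[`, "", "name")),
         communities = stats::setNames(
           communities, vapply(communities, `[[`, "", "name")),
         enzymes = stats::setNames(enzymes, vapply(enzymes, `[[`, "", "name")),
         reference_mass = reference_mass,
         grid = grid, solver = solver),
    class = "cstability_config"
  )
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks structural invariants: unique names, cross-references between
#' enzymes, gates and communities, trait ranges, and signature fraction sums.
#' Returns the configuration invisibly-unchanged on success, errors with a
#' diagnostic otherwise.
#'
#' @param cfg a [cstability_config()].
#' @return `cfg`, invisibly validated.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cstability_config"))
  cls_names <- names(cfg$classes)
  if (anyDuplicated(cls_names)) stop("class names must be unique", call. = FALSE)
  if (anyDuplicated(names(cfg$communities))) {
    stop("community names must be unique", call. = FALSE)
  }
  if (cfg$reference_mass <= 0) stop("reference_mass must be positive", call. = FALSE)
  for (e in cfg$enzymes) {
    if (!e$target %in% cls_names) {
      stop(sprintf("enzyme '%s' targets unknown class '%s'", e$name, e$target),
           call. = FALSE)
    }
    bad <- setdiff(names(e$producers), names(cfg$communities))
    if (length(bad)) {
      stop(sprintf("enzyme '%s' has unknown producer '%s'", e$name, bad[1]),
           call. = FALSE)
    }
  }
  for (cl in cfg$classes) {
    if (inherits(cl$to_accessible, "cs_gate") &&
        !cl$to_accessible$enzyme %in% names(cfg$enzymes)) {
      stop(sprintf("class '%s' gated by unknown enzyme '%s'",
                   cl$name, cl$to_accessible$enzyme), call. = FALSE)
    }
  }
  for (m in cfg$communities) {
    bad <- setdiff(unique(c(names(m$u0), names(m$signature))), cls_names)
    if (length(bad)) {
      stop(sprintf("community '%s' references unknown class '%s'",
                   m$name, bad[1]), call. = FALSE)
    }
    if (sum(m$signature) > 1 + 1e-9) {
      stop(sprintf("community '%s': signature fractions sum to %.3f > 1",
                   m$name, sum(m$signature)), call. = FALSE)
    }
    if (any(m$e0 < 0) || any(m$e0 > 1) || m$m0 < 0 || any(m$u0 < 0) ||
        m$biomass < 0 || any(m$signature < 0)) {
      stop(sprintf("community '%s': traits out of range (0 <= e0 <= 1; ",
                   m$name), "u0, m0, biomass, signature >= 0",
           call. = FALSE)
    }
  }
  with(cfg$solver, stopifnot(dt > 0, t_end >= 0, output_every > 0))
  invisible(cfg)
}

#' @export
print.cstability_config <- function(x, ...) {
  cat(sprintf("<cstability_config> '%s'\n", x$name))
  cat(sprintf("  classes:     %s\n", paste(names(x$classes), collapse = ", ")))
  cat(sprintf("  communities: %s\n", paste(names(x$communities), collapse = ", ")))
  cat(sprintf("  enzymes:     %s\n", paste(names(x$enzymes), collapse = ", ")))
  cat(sprintf("  reference mass %g g_C; dt = %g d, t_end = %g d\n",
              x$reference_mass, x$solver$dt, x$solver$t_end))
  invisible(x)
}

## ---- serialization -------------------------------------------------------

cfg_to_plain <- function(cfg) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) {
      if (inherits(v, "cs_gate")) {
        list(gated = list(coef = v$coef, enzyme = v$enzyme))
      } else if (is.numeric(v) && !is.null(names(v))) {
        as.list(v)
      } else v
    })
  }
  list(name = cfg$name,
       reference_mass = cfg$reference_mass,
       grid = cfg$grid,
       solver = cfg$solver,
       classes = lapply(unname(cfg$classes), strip),
       communities = lapply(unname(cfg$communities), strip),
       enzymes = lapply(unname(cfg$enzymes), strip))
}

plain_to_cfg <- function(x) {
  num <- function(v) {
    if (is.list(v)) v <- unlist(v)
    if (is.null(v)) numeric() else v
  }
  classes <- lapply(x$classes, function(cl) {
    ta <- cl$to_accessible
    if (is.list(ta) && !is.null(ta$gated)) {
      ta <- gated_transfer(ta$gated$coef, ta$gated$enzyme)
    }
    substrate_class(cl$name, cl$accessible, cl$inaccessible,
                    cl$input_accessible, cl$input_inaccessible,
                    ta, cl$to_inaccessible, cl$center_frac, cl$sd_frac)
  })
  communities <- lapply(x$communities, function(m) {
    microbial_community(m$name, m$biomass, num(m$e0), m$m0,
                        num(m$u0), num(m$signature))
  })
  enzymes <- lapply(x$enzymes, function(e) {
    enzyme_family(e$name, e$target, e$tau0, e$alpha, num(e$producers))
  })
  known <- c("name", "reference_mass", "grid", "solver", "classes",
             "communities", "enzymes")
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key '%s'", bad[1]), call. = FALSE)
  }
  cstability_config(classes, communities, enzymes,
                    reference_mass = x$reference_mass,
                    grid = lapply(x$grid, num), solver = lapply(x$solver, num),
                    name = x$name)
}

#' Read / write a configuration as YAML
#'
#' Scenario configurations serialize losslessly to a structured YAML file
#' (numeric values in the same units as the builders); `config_read()`
#' rejects unknown keys.
#'
#' @param cfg a [cstability_config()].
#' @param path file path.
#' @return `config_write()` returns `path` invisibly; `config_read()`
#'   returns a validated [cstability_config()].
#' @export
config_write <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg_to_plain(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  plain_to_cfg(yaml::read_yaml(path))
}

#' Override configuration values by dotted key
#'
#' Applies `key = value` overrides such as `solver.t_end = 100` or
#' `communities.plant_decomposer.m0 = 0.01` to a configuration and
#' revalidates it.  Unknown keys are rejected.
#'
#' @param cfg a [cstability_config()].
#' @param ... named overrides; names are dot-separated paths.
#' @return the modified, revalidated configuration.
#' @export
config_set <- function(cfg, ...) {
  dots <- list(...)
  for (key in names(dots)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (i in seq_along(path)) {
      if (is.null(node[[path[i]]])) {
        stop(sprintf("unknown configuration key '%s'", key), call. = FALSE)
      }
      node <- node[[path[i]]]
    }
    cfg[[path]] <- dots[[key]]
  }
  validate_config(cfg)
  cfg
}
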