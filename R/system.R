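# Sampling-system interface. The threshold engine is agnostic of what it
# samples: it needs an energy, a proposal generator, a validity check, a local
# minimizer and a duplicate test. Two implementations are provided — the full
# crystal system and the analytic toy landscape — so the engine's contracts
# can be verified against landscapes whose barriers are known exactly.

#' Build a sampling system
#'
#' @param energy function(state) -> numeric (unminimized energy)
#' @param propose function(state) -> proposed state (uses the session RNG)
#' @param minimize function(state) -> list(state, energy, converged)
#' @param valid function(state) -> logical (close-contact style pre-check)
#' @param fingerprint function(state) -> cheap comparison object (powder
#'   pattern for crystals); may be NULL
#' @param is_same function(state1, state2, fp1, fp2) -> logical duplicate test
#' @param describe short label for printing
#' @return an `mc_system`
#' @export
mc_system <- function(energy, propose, minimize, valid = function(state) TRUE,
                      fingerprint = NULL, is_same, describe = "system") {
  structure(list(energy = energy, propose = propose, minimize = minimize,
                 valid = valid, fingerprint = fingerprint, is_same = is_same,
                 describe = describe), class = "mc_system")
}

#' Toy-landscape sampling system
#'
#' Uniform steps of half-width `step` on the line; minimization and duplicate
#' identity are analytic.
#' @param tl a [make_toy_landscape()] object
#' @param step proposal half-width (keep well below the well spacing of 1 so
#'   proposals cannot jump across saddles)
#' @return an `mc_system`
#' @export
toy_mc_system <- function(tl, step = 0.1) {
  mc_system(
    energy = function(state) tl$fn(state),
    propose = function(state) state + (stats::runif(1) * 2 - 1) * step,
    minimize = function(state) toy_minimize(tl, state),
    is_same = function(s1, s2, fp1 = NULL, fp2 = NULL) abs(s1 - s2) < 1e-9,
    describe = sprintf("toy landscape (%d wells)", tl$n)
  )
}

#' Crystal sampling system
#'
#' Wires the energy model, move generator, three-step minimizer and two-step
#' duplicate matcher into the threshold engine's interface.
#' @param ff a [force_field()]
#' @param settings an [energy_settings()]
#' @param movespec a [move_spec()]
#' @param criteria a [match_criteria()]
#' @param maxit minimizer iteration budget per stage
#' @return an `mc_system`
#' @export
crystal_mc_system <- function(ff, settings = energy_settings(),
                              movespec = move_spec(),
                              criteria = match_criteria(), maxit = 300) {
  mc_system(
    energy = function(state) lattice_energy(state, ff, settings),
    propose = function(state) {
      pr <- propose_move(state, movespec)
      if (pr$skipped) return(NULL)
      pr$structure
    },
    minimize = function(state) {
      res <- minimize_structure(state, ff, settings, maxit = maxit)
      list(state = res$structure, energy = res$energy,
           converged = res$converged)
    },
    valid = function(state) check_close_contacts(state, ff,
                                                 settings$contact_margin)$ok,
    # fingerprints cache the powder pattern and (lazily) the comparison
    # clusters, so a registry entry is only ever featurized once and clusters
    # are only built when the pattern screen actually matches something
    fingerprint = function(state) {
      fp <- new.env(parent = emptyenv())
      fp$pattern <- simulate_powder_pattern(state)
      fp$pac <- pattern_autocorrelation(fp$pattern)
      fp$formula <- formula_key(state)
      delayedAssign("clusters", cluster_set(state, criteria),
                    assign.env = fp)
      fp
    },
    is_same = function(s1, s2, fp1 = NULL, fp2 = NULL) {
      if (is.null(fp1) || is.null(fp2)) {
        return(is_duplicate(s1, s2, criteria))
      }
      if (fp1$formula != fp2$formula) return(FALSE)
      if (pattern_similarity(fp1$pattern, fp2$pattern,
                             ac1 = fp1$pac, ac2 = fp2$pac) <
            criteria$pattern_threshold) {
        return(FALSE)
      }
      clusters_align(fp1$clusters[[1]], fp2$clusters, criteria) ||
        clusters_align(fp2$clusters[[1]], fp1$clusters, criteria)
    },
    describe = "crystal lattice-energy system"
  )
}
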