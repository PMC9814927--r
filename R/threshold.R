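# The threshold (lid) algorithm. From a minimized seed structure, Monte Carlo
# trajectories are run under a sequence of lid energies: a proposed move is
# accepted iff it passes the validity check and its single-point (unminimized)
# energy stays at or below the current lid. Every accepted state is locally
# minimized and the resulting minimum registered (deduplicated); the walker
# itself continues from the accepted unminimized state, so it can only explore
# the pocket of configuration space below the lid. The lid is raised in fixed
# increments from the minimized energy of the initial structure. When two
# trajectories sample a common minimum, the lid energy at which both have done
# so estimates (from above) the energy barrier between their seeds.

#' Lid schedule
#' @param increment lid increment [kJ/mol], default 5 (use 1 for refinement)
#' @param n_lids number of lid raises
#' @param steps_per_lid attempted Monte Carlo moves per lid
#' @return a `lid_schedule`
#' @export
lid_schedule <- function(increment = 5, n_lids = 10, steps_per_lid = 1000) {
  if (increment <= 0) stop("lid increment must be positive")
  if (steps_per_lid <= 0) stop("steps per lid must be positive")
  if (n_lids < 0) stop("number of lids must be >= 0")
  structure(list(increment = increment, n_lids = n_lids,
                 steps_per_lid = steps_per_lid), class = "lid_schedule")
}

#' Minima registry
#'
#' Mutable registry of unique minima shared between threshold trajectories.
#' Registration deduplicates through the system's duplicate test (guarded by
#' an energy window) and keeps the lower-energy representative on collision.
#' @param energy_window minimized energies differing by more than this skip
#'   the expensive duplicate test entirely [kJ/mol]
#' @return a `minima_registry` (environment)
#' @export
minima_registry <- function(energy_window = 0.5) {
  reg <- new.env(parent = emptyenv())
  reg$entries <- list()
  reg$energy_window <- energy_window
  class(reg) <- "minima_registry"
  reg
}

#' Register a minimum (deduplicated)
#' @param registry a [minima_registry()]
#' @param state minimized state
#' @param energy minimized energy
#' @param system the `mc_system` providing `fingerprint` and `is_same`
#' @return integer id of the (new or matched) registry entry
#' @export
register_minimum <- function(registry, state, energy, system) {
  fp <- if (!is.null(system$fingerprint)) system$fingerprint(state) else NULL
  for (id in seq_along(registry$entries)) {
    e <- registry$entries[[id]]
    if (abs(e$energy - energy) > registry$energy_window) next
    if (system$is_same(state, e$state, fp, e$fingerprint)) {
      if (energy < e$energy - 1e-9) { # keep the lower-energy representative
        e$state <- state; e$energy <- energy; e$fingerprint <- fp
        registry$entries[[id]] <- e
      }
      return(id)
    }
  }
  registry$entries[[length(registry$entries) + 1]] <-
    list(state = state, energy = energy, fingerprint = fp)
  length(registry$entries)
}

#' Minima table of a registry
#' @param registry a [minima_registry()]
#' @return data.frame(id, energy)
#' @export
registry_minima <- function(registry) {
  data.frame(id = seq_along(registry$entries),
             energy = vapply(registry$entries, `[[`, 0, "energy"))
}

#' Run one threshold trajectory
#'
#' @param system an [mc_system()]
#' @param seed_state a converged local minimum under the same system (the run
#'   aborts if re-minimizing the seed moves its energy by more than
#'   `seed_tol`)
#' @param schedule a [lid_schedule()]
#' @param registry a shared [minima_registry()] (created if missing)
#' @param rng_seed integer seed for the trajectory's random stream
#' @param run_id identifier used in logs
#' @param seed_tol tolerance for the seed-convergence precondition [kJ/mol]
#' @param reset_at_lid restart the walker from the seed minimum at every lid
#'   raise instead of continuing from the current state (default FALSE:
#'   continuation, the standard threshold convention)
#' @param keep_states also store every accepted state and its minimum (for
#'   diagnostics; memory grows with the number of accepted moves)
#' @return a `threshold_run`: list with `seed_id`, `base_energy`, `lids`,
#'   `visits` (data.frame id, first_lid_energy, first_lid_index), `log`
#'   (accepted steps), `counts` (per-lid acceptance), `registry`, `rng_seed`
#' @export
run_threshold <- function(system, seed_state, schedule,
                          registry = minima_registry(), rng_seed = NULL,
                          run_id = 1L, seed_tol = 1e-3,
                          reset_at_lid = FALSE, keep_states = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  e_seed <- system$energy(seed_state)
  m0 <- system$minimize(seed_state)
  if (!isTRUE(m0$converged) || abs(m0$energy - e_seed) > seed_tol) {
    stop(sprintf("seed is not a converged minimum (E=%.6f, re-minimized %.6f)",
                 e_seed, m0$energy))
  }
  seed_id <- register_minimum(registry, m0$state, m0$energy, system)
  base <- m0$energy
  lids <- if (schedule$n_lids > 0) base + seq_len(schedule$n_lids) * schedule$increment else numeric(0)

  visits <- new.env(parent = emptyenv())
  assign(as.character(seed_id), c(base, 0), envir = visits) # seed visited at lid 0
  cur <- m0$state
  log_rows <- list()
  kept <- list()
  counts <- data.frame(lid_index = seq_along(lids),
                       lid_energy = as.numeric(lids),
                       attempted = integer(length(lids)),
                       accepted = integer(length(lids)),
                       minimized = integer(length(lids)),
                       failed_min = integer(length(lids)))
  for (k in seq_along(lids)) {
    lid <- lids[k]
    if (reset_at_lid) cur <- m0$state
    for (step in seq_len(schedule$steps_per_lid)) {
      counts$attempted[k] <- counts$attempted[k] + 1L
      prop <- system$propose(cur)
      if (is.null(prop) || !system$valid(prop)) next
      e <- system$energy(prop)
      if (!is.finite(e) || e > lid) next
      cur <- prop # accepted: walker continues from the unminimized state
      counts$accepted[k] <- counts$accepted[k] + 1L
      mres <- system$minimize(prop)
      if (!isTRUE(mres$converged)) {
        counts$failed_min[k] <- counts$failed_min[k] + 1L
        next # discard the trajectory point for registry purposes, keep walking
      }
      counts$minimized[k] <- counts$minimized[k] + 1L
      id <- register_minimum(registry, mres$state, mres$energy, system)
      key <- as.character(id)
      if (!exists(key, envir = visits)) assign(key, c(lid, k), envir = visits)
      log_rows[[length(log_rows) + 1]] <-
        c(lid_index = k, lid_energy = lid, step = step, e_unmin = e,
          e_min = mres$energy, min_id = id)
      if (keep_states) {
        kept[[length(kept) + 1]] <- list(lid = lid, step = step,
                                         state = prop, minimum = mres$state)
      }
    }
  }
  vkeys <- ls(visits)
  vmat <- t(vapply(vkeys, function(k) get(k, envir = visits), numeric(2)))
  visits_df <- data.frame(id = as.integer(vkeys),
                          first_lid_energy = vmat[, 1],
                          first_lid_index = as.integer(vmat[, 2]))
  visits_df <- visits_df[order(visits_df$id), , drop = FALSE]
  rownames(visits_df) <- NULL
  log_df <- if (length(log_rows)) {
    as.data.frame(do.call(rbind, log_rows))
  } else {
    data.frame(lid_index = integer(0), lid_energy = numeric(0),
               step = integer(0), e_unmin = numeric(0), e_min = numeric(0),
               min_id = integer(0))
  }
  structure(list(run_id = run_id, seed_id = seed_id, base_energy = base,
                 schedule = schedule, lids = lids, visits = visits_df,
                 log = log_df, counts = counts, registry = registry,
                 rng_seed = rng_seed,
                 states = if (keep_states) kept else NULL),
            class = "threshold_run")
}

#' Seed-to-seed connection events between trajectories
#'
#' Two trajectories are connected at the lowest lid energy at which both have
#' sampled a common registry minimum; the event links their seed minima.
#' Transitive closure is left to the disconnectivity layer.
#' @param runs list of [run_threshold()] results sharing one registry
#' @return data.frame(a, b, lid, via): seed minimum ids, connection lid
#'   energy, witnessing common minimum
#' @export
detect_connections <- function(runs) {
  out <- list()
  if (length(runs) >= 2) {
    for (i in seq_len(length(runs) - 1)) for (j in (i + 1):length(runs)) {
      vi <- runs[[i]]$visits; vj <- runs[[j]]$visits
      common <- intersect(vi$id, vj$id)
      if (!length(common)) next
      lid_ab <- vapply(common, function(m) {
        max(vi$first_lid_energy[vi$id == m], vj$first_lid_energy[vj$id == m])
      }, 0)
      best <- which.min(lid_ab)
      if (runs[[i]]$seed_id == runs[[j]]$seed_id) next
      out[[length(out) + 1]] <- data.frame(
        a = runs[[i]]$seed_id, b = runs[[j]]$seed_id,
        lid = lid_ab[best], via = common[best])
    }
  }
  if (!length(out)) {
    return(data.frame(a = integer(0), b = integer(0), lid = numeric(0),
                      via = integer(0)))
  }
  do.call(rbind, out)
}

#' All pairwise connections implied by the trajectories
#'
#' Within one trajectory, any two visited minima are connected at the larger
#' of their first-visit lids (the walker sampled both below it). Cross-run
#' links follow through shared minima during graph construction. This is the
#' connection set handed to [build_graph()].
#' @param runs list of `threshold_run`s sharing one registry
#' @return data.frame(a, b, lid)
#' @export
run_connections <- function(runs) {
  out <- list()
  for (r in runs) {
    v <- r$visits
    if (nrow(v) < 2) next
    pr <- utils::combn(seq_len(nrow(v)), 2)
    out[[length(out) + 1]] <- data.frame(
      a = v$id[pr[1, ]], b = v$id[pr[2, ]],
      lid = pmax(v$first_lid_energy[pr[1, ]], v$first_lid_energy[pr[2, ]]))
  }
  if (!length(out)) {
    return(data.frame(a = integer(0), b = integer(0), lid = numeric(0)))
  }
  res <- do.call(rbind, out)
  # collapse duplicates keeping the lowest lid per unordered pair
  key <- paste(pmin(res$a, res$b), pmax(res$a, res$b))
  res <- res[order(key, res$lid), ]
  res[!duplicated(paste(pmin(res$a, res$b), pmax(res$a, res$b))), , drop = FALSE]
}

#' Merge runs onto a common lid grid
#'
#' Trajectories started from different seeds carry different lid grids. For a
#' joint disconnectivity graph a new grid is laid from the lowest seed energy
#' with the common increment, and every connection lid is rounded UP to the
#' closest grid energy.
#' @param runs list of `threshold_run`s
#' @param connections optional connection table (default:
#'   [run_connections()] of the runs)
#' @return list(grid, connections) with remapped lid values
#' @export
merge_onto_common_grid <- function(runs, connections = NULL) {
  incs <- vapply(runs, function(r) r$schedule$increment, 0)
  if (length(unique(incs)) != 1) {
    stop("runs use different lid increments; cannot merge onto one grid")
  }
  inc <- incs[1]
  base <- min(vapply(runs, `[[`, 0, "base_energy"))
  top <- max(c(vapply(runs, function(r) max(c(r$lids, r$base_energy)), 0)))
  grid <- base + inc * (0:ceiling((top - base) / inc + 1e-9))
  if (is.null(connections)) connections <- run_connections(runs)
  snap <- function(x) grid[findInterval(x - 1e-9, grid) + 1]
  if (nrow(connections)) connections$lid <- vapply(connections$lid, snap, 0)
  list(grid = grid, connections = connections)
}

#' @export
print.threshold_run <- function(x, ...) {
  cat(sprintf("threshold run %s: seed minimum #%d at %.4f kJ/mol, %d lids x %d steps, %d minima visited\n",
              as.character(x$run_id), x$seed_id, x$base_energy,
              length(x$lids), x$schedule$steps_per_lid, nrow(x$visits)))
  invisible(x)
}
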