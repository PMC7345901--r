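#' Configuration of the interaction-space repertoire simulation
#'
#' Collects every tunable parameter of the agent-based B-cell simulation.
#' Clones live on a `shape_dim`-dimensional unit sphere of epitope-shape
#' directions; their radial coordinate is the binding free energy
#' `dg = eps0 * r_bonds * alignment` (kJ/mol), so each well-aligned
#' noncovalent bond contributes `eps0` (default 2.577, the thermal energy
#' RT at 310 K). Antigen availabilities are exponentially distributed with
#' rate `lam`; the angular cap a clone can engage shrinks with affinity as
#' `theta(dg) = angular_c / dg` (higher resolution, narrower shape
#' discrimination).
#'
#' @param shape_dim Dimension D >= 2 of the shape space (default 8).
#' @param n_antigens Number of antigenic sites sampled on the sphere.
#' @param lam Rate of the exponential distribution of antigen base
#'   availability (default the golden ratio, 1.618034).
#' @param influx_per_step New clones emitted by the bone marrow per step.
#' @param r0 Bonds of a freshly minted receptor (default 3).
#' @param eps0 Energy per well-aligned bond, kJ/mol.
#' @param division_rate Per-cell division probability per step, scaled by
#'   receptor engagement.
#' @param death_rate Named per-stage per-cell death probability per step.
#' @param b1_fraction Fraction of influx committed to the innate-like B1
#'   lineage (stable, never enters germinal centres).
#' @param gc_pull Fractional pull of a germinal-centre mutation toward the
#'   driving antigen direction.
#' @param gc_mutation_step Standard deviation of the isotropic component of
#'   a germinal-centre angular mutation.
#' @param gc_cycles Hard cap on mutation-selection cycles per clone.
#' @param gc_trigger Minimum receptor engagement probability required to
#'   enter a germinal centre.
#' @param gc_entry_dg Minimum binding energy required to enter a germinal
#'   centre; `NULL` (default) uses the naive shell energy `r0 * eps0`, the
#'   boundary of the circulating repertoire.
#' @param clearance_depth Affinity maturation proceeds while the clone's
#'   K_D exceeds `clearance_depth` times the antigen's base availability;
#'   maturation stops once the clone can hold free antigen this far below
#'   its unregulated level.
#' @param clear_tol Relative tolerance on the cleared-antigen condition
#'   `free <= K_D` that triggers retraction (free relaxes to K_D from
#'   above, so an exact inequality would never fire).
#' @param angular_c Angular resolution constant `c` in
#'   `theta(dg) = c / dg`; `NULL` (default) chooses `c` so that a naive
#'   cap covers `naive_cap_fraction` of the sphere.
#' @param naive_cap_fraction Sphere fraction covered by a naive clone's
#'   cap, used to derive `angular_c` (default 1%).
#' @param max_clone_size Carrying capacity of a clone (cells).
#' @param rho Per-step fractional relaxation of free antigen toward its
#'   regulated target.
#' @param shell_width Width of the iso-energy shells used in summaries,
#'   kJ/mol.
#' @param n_steps Number of synchronous simulation steps.
#' @param seed RNG seed for the run.
#' @param temperature Temperature (K) of the embedded [thermo_context].
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_antigens = 10, n_steps = 50)
#' @export
sim_config <- function(shape_dim = 8,
                       n_antigens = 100,
                       lam = 1.618034,
                       influx_per_step = 25,
                       r0 = 3,
                       eps0 = 2.577,
                       division_rate = 0.3,
                       death_rate = c(immature = 0.08, naiveB2 = 0.08,
                                      GC = 0.02, MBC = 0, LLPC = 0, B1 = 0),
                       b1_fraction = 0.05,
                       gc_pull = 0.2,
                       gc_mutation_step = 0.02,
                       gc_cycles = 40,
                       gc_trigger = 0.5,
                       gc_entry_dg = NULL,
                       clearance_depth = 0.01,
                       clear_tol = 0.1,
                       angular_c = NULL,
                       naive_cap_fraction = 0.01,
                       max_clone_size = 10000,
                       rho = 0.5,
                       shell_width = 2.577,
                       n_steps = 500,
                       seed = 0,
                       temperature = 310) {
  if (shape_dim < 2) stop("`shape_dim` must be >= 2")
  if (lam <= 0) stop("`lam` must be > 0")
  rates <- c(influx_per_step, division_rate, death_rate, b1_fraction,
             gc_pull, gc_mutation_step, gc_trigger, clearance_depth,
             clear_tol, rho)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and >= 0")
  }
  stages <- c("immature", "naiveB2", "GC", "MBC", "LLPC", "B1")
  if (!all(stages %in% names(death_rate))) {
    stop("`death_rate` must name every stage: ",
         paste(stages, collapse = ", "))
  }
  if (is.null(gc_entry_dg)) gc_entry_dg <- r0 * eps0
  if (is.null(angular_c)) {
    angular_c <- cap_half_angle(shape_dim, naive_cap_fraction) * r0 * eps0
  }
  structure(
    list(shape_dim = shape_dim, n_antigens = n_antigens, lam = lam,
         influx_per_step = influx_per_step, r0 = r0, eps0 = eps0,
         division_rate = division_rate, death_rate = death_rate,
         b1_fraction = b1_fraction, gc_pull = gc_pull,
         gc_mutation_step = gc_mutation_step, gc_cycles = gc_cycles,
         gc_trigger = gc_trigger, gc_entry_dg = gc_entry_dg,
         clearance_depth = clearance_depth, clear_tol = clear_tol,
         angular_c = angular_c, max_clone_size = max_clone_size, rho = rho,
         shell_width = shell_width, n_steps = n_steps, seed = seed,
         temperature = temperature,
         ctx = thermo_context(temperature)),
    class = "sim_config"
  )
}

#' Half-angle of a spherical cap covering a given fraction of the sphere
#'
#' Solves for the geodesic half-angle `theta` such that a cap on the unit
#' sphere in `d` dimensions covers fraction `fraction` of its surface.
#'
#' @param d Dimension of the ambient space, >= 2.
#' @param fraction Surface fraction in (0, 1).
#' @return Half-angle in radians.
#' @export
cap_half_angle <- function(d, fraction) {
  if (d < 2) stop("`d` must be >= 2")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  total <- integrate(function(t) sin(t)^(d - 2), 0, pi)$value
  uniroot(function(th) {
    integrate(function(t) sin(t)^(d - 2), 0, th)$value / total - fraction
  }, c(1e-8, pi - 1e-8), tol = 1e-12)$root
}

#' Uniform random directions on the unit sphere
#'
#' @param n Number of directions.
#' @param d Dimension.
#' @return An `n x d` matrix of unit row vectors.
#' @export
runif_sphere <- function(n, d) {
  m <- matrix(rnorm(n * d), nrow = n)
  m / sqrt(rowSums(m^2))
}

empty_clones <- function() {
  data.frame(id = integer(), stage = character(), r_bonds = integer(),
             dg = numeric(), dg_birth = numeric(), size = integer(),
             parent = integer(), subnetwork = integer(),
             gc_rounds = integer(), birth = integer(),
             stringsAsFactors = FALSE)
}

#' Initialize antigens and an empty repertoire
#'
#' Samples `n_antigens` antigenic sites with directions uniform on the
#' unit sphere and base availabilities drawn from Exponential(`lam`); free
#' concentrations start equal to base. The repertoire starts empty.
#' Deterministic under the config seed when called through
#' [simulate_repertoire]; call [set.seed] yourself for standalone use.
#'
#' @param config A [sim_config].
#' @return A `repertoire_state`: a list with elements `clones` (data frame),
#'   `cdir` (clone direction matrix), `antigens` (data frame with `base`,
#'   `free`), `adir` (antigen direction matrix), `t` (step counter),
#'   `next_id`, `lineage` (cumulative stage-transition counts) and
#'   `ledger` (per-step cell bookkeeping).
#' @export
init_space <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_antigens
  adir <- if (n > 0) runif_sphere(n, config$shape_dim) else
    matrix(numeric(), 0, config$shape_dim)
  antigens <- data.frame(base = if (n > 0) rexp(n, config$lam) else numeric())
  antigens$free <- antigens$base
  structure(
    list(clones = empty_clones(),
         cdir = matrix(numeric(), 0, config$shape_dim),
         antigens = antigens, adir = adir,
         t = 0L, next_id = 1L,
         lineage = c(CLP = 0L, proB = 0L, preB = 0L, immature = 0L),
         ledger = data.frame(t = integer(), influx = integer(),
                             divisions = integer(), deaths = integer(),
                             apoptosis = integer(), total = integer())),
    class = "repertoire_state"
  )
}

#' @export
print.repertoire_state <- function(x, ...) {
  cat("repertoire_state: step", x$t, "-", nrow(x$clones), "clones,",
      nrow(x$antigens), "antigens\n")
  if (nrow(x$clones)) print(table(x$clones$stage))
  invisible(x)
}

#' Bone-marrow influx of new clones
#'
#' Adds `n_new` clones at stage `immature` (a configurable fraction at the
#' stable innate-like `B1` stage) with uniformly random directions,
#' `r_bonds = r0` and `dg = r0 * eps0`. The CLP -> proB -> preB -> immature
#' progression is recorded in the state's lineage counters; the clones'
#' `dg_birth` records the energy inherited from the (zero-energy) CLP
#' origin, so radial monotonicity can be audited along every lineage.
#'
#' @param state A `repertoire_state`.
#' @param config A [sim_config].
#' @param n_new Number of new clones (default `config$influx_per_step`).
#' @return The updated state.
#' @export
bone_marrow_influx <- function(state, config, n_new = config$influx_per_step) {
  stopifnot(inherits(state, "repertoire_state"))
  if (n_new < 0) stop("`n_new` must be >= 0")
  if (n_new == 0) return(state)
  nd <- runif_sphere(n_new, config$shape_dim)
  b1 <- runif(n_new) < config$b1_fraction
  new <- data.frame(
    id = state$next_id + seq_len(n_new) - 1L,
    stage = ifelse(b1, "B1", "immature"),
    r_bonds = as.integer(config$r0),
    dg = config$r0 * config$eps0,
    dg_birth = config$r0 * config$eps0,
    size = 1L,
    parent = NA_integer_,
    subnetwork = NA_integer_,
    gc_rounds = 0L,
    birth = state$t + 1L,
    stringsAsFactors = FALSE
  )
  state$next_id <- state$next_id + as.integer(n_new)
  state$clones <- rbind(state$clones, new)
  state$cdir <- rbind(state$cdir, nd)
  state$lineage <- state$lineage + as.integer(n_new)
  state
}

kd_of <- function(dg, config) exp(-dg / config$ctx$rt)

# clones x antigens matrix of engagement probabilities
engagement_matrix <- function(state, config) {
  n <- nrow(state$clones)
  m <- nrow(state$antigens)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  cosm <- state$cdir %*% t(state$adir)
  ang <- acos(pmin(pmax(cosm, -1), 1))
  within <- ang <= config$angular_c / state$clones$dg
  kd <- kd_of(state$clones$dg, config)
  free <- matrix(state$antigens$free, n, m, byrow = TRUE)
  occ <- free / (free + kd) # recycles kd down columns (per clone)
  pmin(within * occ, 1)
}

#' Probability that a clone engages an antigen
#'
#' Zero outside the clone's angular cap `theta(dg) = angular_c / dg`;
#' inside the cap it is the receptor-occupancy probability
#' `free / (free + K_D(dg))`, capped at 1.
#'
#' @param clone_dir Unit direction vector of the clone.
#' @param clone_dg Binding energy of the clone.
#' @param antigen_dir Unit direction vector of the antigen.
#' @param free_concentration Current free antigen level, >= 0.
#' @param config A [sim_config].
#' @return Engagement probability in `[0, 1]`.
#' @export
engagement_probability <- function(clone_dir, clone_dg, antigen_dir,
                                   free_concentration, config) {
  ang <- acos(min(max(sum(clone_dir * antigen_dir), -1), 1))
  if (ang > config$angular_c / clone_dg) return(0)
  kd <- kd_of(clone_dg, config)
  min(free_concentration / (free_concentration + kd), 1)
}

#' One germinal-centre mutation-selection cycle for a clone
#'
#' Proposes one additional noncovalent bond together with an angular move
#' toward (fraction `gc_pull`) and around (Gaussian step, sd
#' `gc_mutation_step`) the driving antigen. The proposal is accepted if and
#' only if the resulting affinity `dg = eps0 * (r_bonds + 1) * alignment`
#' strictly increases (strict selection); rejected proposals leave the
#' clone unchanged except for the cycle counter.
#'
#' @param clone A one-row slice of the clone table (list or data frame row)
#'   with `r_bonds`, `dg`, `gc_rounds`.
#' @param clone_dir Current unit direction of the clone.
#' @param antigen_dir Unit direction of the driving antigen.
#' @param config A [sim_config].
#' @return List with updated `r_bonds`, `dg`, `gc_rounds`, `dir` and the
#'   logical `accepted`.
#' @export
germinal_center_step <- function(clone, clone_dir, antigen_dir, config) {
  prop <- clone_dir + config$gc_pull * (antigen_dir - clone_dir) +
    rnorm(length(clone_dir), 0, config$gc_mutation_step)
  prop <- prop / sqrt(sum(prop^2))
  alignment <- sum(prop * antigen_dir)
  dg_new <- config$eps0 * (clone$r_bonds + 1) * max(alignment, 0)
  if (dg_new > clone$dg) {
    list(r_bonds = clone$r_bonds + 1L, dg = dg_new,
         gc_rounds = clone$gc_rounds + 1L, dir = prop, accepted = TRUE)
  } else {
    list(r_bonds = clone$r_bonds, dg = clone$dg,
         gc_rounds = clone$gc_rounds + 1L, dir = clone_dir,
         accepted = FALSE)
  }
}

# maturation drive: K_D still above clearance_depth x base availability
gc_active <- function(state, config, i) {
  s <- state$clones$subnetwork[i]
  state$clones$gc_rounds[i] < config$gc_cycles &&
    kd_of(state$clones$dg[i], config) >
      config$clearance_depth * state$antigens$base[s]
}

#' Retraction of cleared germinal-centre responses
#'
#' For every antigen whose free concentration has fallen to the
#' dissociation constant of its best germinal-centre clone (within
#' `clear_tol`), the response retracts: the highest-energy clone becomes
#' the subnetwork's long-lived plasma cell (LLPC, one per subnetwork,
#' secreting thereafter), the remaining members become resting memory B
#' cells at their current energy with minimal size, and the effector
#' excess is removed by apoptosis (recorded in the ledger).
#'
#' @param state A `repertoire_state`.
#' @param config A [sim_config].
#' @return The updated state (with `state$apoptosis_last` cell count).
#' @export
retract <- function(state, config) {
  cl <- state$clones
  state$apoptosis_last <- 0L
  gc_subs <- unique(cl$subnetwork[cl$stage == "GC"])
  gc_subs <- gc_subs[!is.na(gc_subs)]
  if (!length(gc_subs)) return(state)
  kd <- kd_of(cl$dg, config)
  removed <- 0L
  for (s in gc_subs) {
    mem <- which(cl$stage == "GC" & cl$subnetwork == s)
    best <- mem[which.max(cl$dg[mem])]
    if (state$antigens$free[s] <= (1 + config$clear_tol) * kd[best]) {
      removed <- removed + sum(pmax(cl$size[mem] - 1L, 0L))
      cl$stage[mem] <- "MBC"
      cl$size[mem] <- 1L
      cl$stage[best] <- "LLPC"
    }
  }
  state$clones <- cl
  state$apoptosis_last <- removed
  state
}

#' Relax free antigen toward its regulated level
#'
#' Each antigen's free concentration relaxes by factor `rho` per step
#' toward `min(base, K_D_best)` where `K_D_best` is the dissociation
#' constant of the best secreting clone (germinal-centre effector or
#' long-lived plasma cell) whose angular cap covers the antigen. Antigens
#' with no covering secretor stay at (or relax back to) their base level;
#' free never exceeds base.
#'
#' @param state A `repertoire_state`.
#' @param config A [sim_config].
#' @return The updated state.
#' @export
update_antigen <- function(state, config) {
  m <- nrow(state$antigens)
  if (m == 0L) return(state)
  cl <- state$clones
  sec <- which(cl$stage %in% c("GC", "LLPC"))
  target <- state$antigens$base
  if (length(sec)) {
    cosm <- state$cdir[sec, , drop = FALSE] %*% t(state$adir)
    ang <- acos(pmin(pmax(cosm, -1), 1))
    covered <- ang <= config$angular_c / cl$dg[sec]
    kd <- kd_of(cl$dg[sec], config)
    for (a in seq_len(m)) {
      ci <- which(covered[, a])
      if (length(ci)) target[a] <- min(target[a], min(kd[ci]))
    }
  }
  free <- state$antigens$free + config$rho * (target - state$antigens$free)
  state$antigens$free <- pmin(pmax(free, 0), state$antigens$base)
  state
}

#' Advance the simulation by one synchronous step
#'
#' Order of events: (1) bone-marrow influx; (2) clonal expansion - each
#' expandable clone grows by `Binomial(size, division_rate * engagement)`
#' and shrinks by `Binomial(size, death_rate[stage])`, capped at the
#' carrying capacity, with extinct clones removed; (3) immature clones
#' age into naive B2; (4) germinal-centre entry for engaged naive clones
#' above the energy gate; (5) one mutation-selection cycle for every
#' active germinal-centre clone; (6) retraction of cleared responses;
#' (7) antigen relaxation. The cell ledger records influx, divisions,
#' deaths and retraction apoptosis so that cell conservation can be
#' audited per step.
#'
#' @param state A `repertoire_state`.
#' @param config A [sim_config].
#' @return The updated state.
#' @export
sim_step <- function(state, config) {
  stopifnot(inherits(state, "repertoire_state"),
            inherits(config, "sim_config"))
  prev_total <- sum(state$clones$size)
  state <- bone_marrow_influx(state, config)
  influx_cells <- sum(state$clones$size) - prev_total
  cl <- state$clones
  n <- nrow(cl)

  divisions <- deaths <- 0L
  if (n > 0L) {
    e <- engagement_matrix(state, config)
    emax <- if (ncol(e)) apply(e, 1, max) else rep(0, n)
    edrive <- if (ncol(e)) max.col(e, ties.method = "first") else
      rep(NA_integer_, n)

    expandable <- cl$stage %in% c("immature", "naiveB2", "GC")
    born <- ifelse(expandable,
                   rbinom(n, cl$size, pmin(config$division_rate * emax, 1)),
                   0L)
    dead <- rbinom(n, cl$size, config$death_rate[cl$stage])
    size_new <- pmin(cl$size + born - dead, config$max_clone_size)
    # cells beyond carrying capacity are never created
    divisions <- sum(size_new - cl$size + dead)
    deaths <- sum(dead)
    cl$size <- size_new
    alive <- cl$size > 0L
    deaths <- deaths # extinct clones die through the same binomial
    cl <- cl[alive, , drop = FALSE]
    state$cdir <- state$cdir[alive, , drop = FALSE]
    emax <- emax[alive]
    edrive <- edrive[alive]
    n <- nrow(cl)

    # maturation of surviving bone-marrow output
    promote <- cl$stage == "immature" & cl$birth < state$t + 1L
    cl$stage[promote] <- "naiveB2"

    # germinal-centre entry: engaged naive clones at/beyond the energy gate
    entry <- cl$stage == "naiveB2" & emax >= config$gc_trigger &
      cl$dg >= config$gc_entry_dg
    cl$stage[entry] <- "GC"
    cl$subnetwork[entry] <- edrive[entry]
    cl$gc_rounds[entry] <- 0L
    state$clones <- cl

    for (i in which(cl$stage == "GC")) {
      if (!gc_active(state, config, i)) next
      upd <- germinal_center_step(
        state$clones[i, ], state$cdir[i, ],
        state$adir[state$clones$subnetwork[i], ], config
      )
      state$clones$r_bonds[i] <- upd$r_bonds
      state$clones$dg[i] <- upd$dg
      state$clones$gc_rounds[i] <- upd$gc_rounds
      state$cdir[i, ] <- upd$dir
    }
  }

  state <- retract(state, config)
  state <- update_antigen(state, config)
  state$t <- state$t + 1L
  state$ledger <- rbind(state$ledger, data.frame(
    t = state$t, influx = influx_cells, divisions = divisions,
    deaths = deaths, apoptosis = state$apoptosis_last,
    total = sum(state$clones$size)))
  state
}

#' Run the full repertoire simulation
#'
#' Seeds the RNG from the config, initializes the interaction space and
#' advances `n_steps` synchronous steps. Identical configs (including the
#' seed) reproduce identical final states.
#'
#' @param config A [sim_config].
#' @param verbose Print per-100-step progress counts.
#' @return The final `repertoire_state`.
#' @examples
#' st <- simulate_repertoire(sim_config(n_antigens = 10, n_steps = 30))
#' summarize_repertoire(st, sim_config(n_antigens = 10, n_steps = 30))
#' @export
simulate_repertoire <- function(config = sim_config(), verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_space(config)
  for (step in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    if (verbose && step %% 100 == 0) {
      message("step ", step, ": ", nrow(state$clones), " clones, ",
              sum(state$clones$stage == "LLPC"), " LLPC")
    }
  }
  state
}

#' Summaries of a simulated repertoire
#'
#' Computes per-stage clone counts, clone counts per iso-energy shell
#' (`shell = floor(dg / shell_width)`), and the per-clone table of binding
#' energies and system equilibrium constants
#' `K_sys = exp((dg - mean(dg)) / RT)` using the population mean energy as
#' the system reference. When at least 10 clones lie above `K_sys = 1`, a
#' Hill fit of the emergent upper-tail exponent is included, with the
#' cutoff at the median of the exceedances (only the asymptotic tail is
#' fitted).
#'
#' @param state A `repertoire_state`.
#' @param config A [sim_config].
#' @return An object of class `repertoire_summary`: list with
#'   `stage_counts`, `shell_counts`, `mean_dg`, `clone_table` (id, stage,
#'   dg, ksys), `tail_fit` (or `NULL`) and `regulation` (per-antigen free
#'   level, best covering secretor K_D and their log10 ratio).
#' @export
summarize_repertoire <- function(state, config) {
  stopifnot(inherits(state, "repertoire_state"),
            inherits(config, "sim_config"))
  cl <- state$clones
  stages <- c("immature", "naiveB2", "B1", "GC", "MBC", "LLPC")
  stage_counts <- setNames(integer(length(stages)), stages)
  if (nrow(cl)) {
    tab <- table(factor(cl$stage, levels = stages))
    stage_counts[names(tab)] <- as.integer(tab)
  }
  if (nrow(cl) == 0L) {
    return(structure(
      list(stage_counts = stage_counts, shell_counts = integer(),
           mean_dg = NA_real_,
           clone_table = data.frame(id = integer(), stage = character(),
                                    dg = numeric(), ksys = numeric()),
           tail_fit = NULL,
           regulation = data.frame(antigen = integer(), free = numeric(),
                                   kd_best = numeric(),
                                   log10_ratio = numeric())),
      class = "repertoire_summary"))
  }
  mean_dg <- mean(cl$dg)
  shell <- floor(cl$dg / config$shell_width)
  shell_counts <- table(shell)
  ksys <- ksys_from_dg(cl$dg, mean_dg, config$ctx)
  clone_table <- data.frame(id = cl$id, stage = cl$stage, dg = cl$dg,
                            ksys = ksys, stringsAsFactors = FALSE)
  exceed <- ksys[ksys > 1]
  tail_fit <- NULL
  if (length(exceed) >= 20L) {
    tail_fit <- tryCatch(
      fit_tail_exponent(exceed, k_min = median(exceed)),
      error = function(e) NULL)
  }
  regulation <- regulation_table(state, config)
  structure(
    list(stage_counts = stage_counts,
         shell_counts = shell_counts,
         mean_dg = mean_dg,
         clone_table = clone_table,
         tail_fit = tail_fit,
         regulation = regulation),
    class = "repertoire_summary"
  )
}

# per-antigen regulation report restricted to antigens covered by an LLPC
regulation_table <- function(state, config) {
  cl <- state$clones
  sec <- which(cl$stage == "LLPC")
  out <- data.frame(antigen = integer(), free = numeric(),
                    kd_best = numeric(), log10_ratio = numeric())
  if (!length(sec) || nrow(state$antigens) == 0L) return(out)
  cosm <- state$cdir[sec, , drop = FALSE] %*% t(state$adir)
  ang <- acos(pmin(pmax(cosm, -1), 1))
  covered <- ang <= config$angular_c / cl$dg[sec]
  kd <- kd_of(cl$dg[sec], config)
  for (a in seq_len(nrow(state$antigens))) {
    ci <- which(covered[, a])
    if (!length(ci)) next
    kd_best <- min(kd[ci])
    out <- rbind(out, data.frame(
      antigen = a, free = state$antigens$free[a], kd_best = kd_best,
      log10_ratio = log10(state$antigens$free[a] / kd_best)))
  }
  out
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("repertoire_summary\n  stages:\n")
  print(x$stage_counts)
  cat("  mean dg:", format(x$mean_dg), "\n")
  if (!is.null(x$tail_fit)) {
    cat(sprintf("  emergent K_sys tail exponent: %.3f (n_tail = %d)\n",
                x$tail_fit$alpha, x$tail_fit$n_tail))
  }
  if (nrow(x$regulation)) {
    cat(sprintf("  regulated antigens: %d, max |log10(free/K_D)| = %.3g\n",
                nrow(x$regulation), max(abs(x$regulation$log10_ratio))))
  }
  invisible(x)
}
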