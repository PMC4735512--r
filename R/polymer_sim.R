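#' Simulation parameters for the strings-and-binders chromatin model
#'
#' Builds the parameter set for the lattice Monte-Carlo simulator. The
#' chromatin fibre is a self-avoiding polymer of `n_nodes` lattice nodes;
#' `N_endog` endogenous Ph molecules and `N_exog` exogenous molecules
#' (wild-type Ph or the polymerization-dead Ph-ML, depending on
#' `model_variant`) diffuse in a well-mixed reservoir, bind and unbind nodes
#' with mass-action kinetics scaled by each node's affinity, and form or
#' break bridge bonds between molecules bound at spatially neighbouring
#' nodes.
#'
#' Model variants:
#' \describe{
#'   \item{`baseline`}{endogenous Ph only (or exogenous Ph with default
#'     kinetics); spreading limited to `N_max` molecules per node.}
#'   \item{`weak_binding_ML`}{exogenous molecules are Ph-ML with a 10-fold
#'     higher dissociation rate (unless `k_d_exog` is supplied); no capping.}
#'   \item{`capping_ML`}{exogenous molecules are Ph-ML with wild-type
#'     kinetics, but each Ph-ML that joins a cluster removes one interaction
#'     surface from a resident Ph; association to a fully capped cluster is
#'     blocked and capped molecules cannot bridge.}
#'   \item{`wt_limited`}{exogenous molecules are wild-type Ph; spreading
#'     stays limited to `N_max` per node.}
#'   \item{`wt_unlimited`}{exogenous molecules are wild-type Ph and the
#'     per-node occupancy cap is removed.}
#' }
#'
#' All kinetic parameters are per-step probabilities; `E_bond` is the energy
#' of one binder-binder bridge bond in units of thermal energy (kT).
#'
#' @param n_nodes number of polymer nodes (default 400).
#' @param N_endog,N_exog endogenous / exogenous molecule counts.
#' @param k_a_endog,k_d_endog,k_a_exog,k_d_exog association / dissociation
#'   kinetics. `k_a` is the per-step binding hazard contributed by one free
#'   molecule; `k_d` is the per-step dissociation probability of a lone
#'   bound molecule (dissociation is slowed in proportion to node occupancy
#'   because polymerization stabilizes resident molecules). Exogenous
#'   kinetics default to the endogenous values except in the weak-binding
#'   variant.
#' @param k_join,k_break bridge-bond formation / breakage probabilities.
#' @param E_bond bond energy (kT) governing Metropolis acceptance of
#'   bond-breaking polymer moves.
#' @param N_max per-node occupancy cap (`Inf` for unlimited spreading).
#' @param neighbor_radius lattice distance within which bound molecules at
#'   two nodes can bridge (default `sqrt(3)`, the touching 3x3x3
#'   neighbourhood).
#' @param model_variant one of `"baseline"`, `"weak_binding_ML"`,
#'   `"capping_ML"`, `"wt_unlimited"`, `"wt_limited"`.
#' @param n_steps Monte-Carlo steps per iteration (default 5000).
#' @param n_iterations independent replicate runs (default 50).
#' @param snapshot_every steps between recorded snapshots after burn-in.
#' @param burnin_frac fraction of steps discarded before snapshots.
#' @param n_surfaces interaction surfaces per molecule (default 1; each
#'   surface holds one bridge bond or one cap).
#' @param diameter_scale length per molecule^(1/3) used to convert cluster
#'   molecule counts to diameters (arbitrary units, default 30).
#' @param seed base random seed; iteration `i` of [run_simulation()] uses
#'   `seed + i`.
#' @return A list of class `sim_params`.
#' @seealso [run_simulation()], [run_variant_sweep()]
#' @export
sim_params <- function(n_nodes = 400, N_endog = 60, N_exog = 0,
                       k_a_endog = 0.002, k_d_endog = 0.01,
                       k_a_exog = NULL, k_d_exog = NULL,
                       k_join = 0.005, k_break = 0.2, E_bond = 1.0,
                       N_max = 15, neighbor_radius = sqrt(3),
                       model_variant = c("baseline", "weak_binding_ML",
                                         "capping_ML", "wt_unlimited",
                                         "wt_limited"),
                       n_steps = 5000, n_iterations = 50,
                       snapshot_every = 50, burnin_frac = 0.5,
                       n_surfaces = 1, diameter_scale = 30, seed = 1L) {
  model_variant <- match.arg(model_variant)
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (E_bond < 0) stop("E_bond must be >= 0")
  if (N_endog < 0 || N_exog < 0) stop("binder counts must be >= 0")

  if (is.null(k_a_exog)) k_a_exog <- k_a_endog
  if (is.null(k_d_exog)) {
    k_d_exog <- if (model_variant == "weak_binding_ML") 10 * k_d_endog
                else k_d_endog
  }
  for (nm in c("k_a_endog", "k_d_endog", "k_a_exog", "k_d_exog",
               "k_join", "k_break")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (model_variant == "wt_unlimited") N_max <- Inf

  p <- list(
    n_nodes = as.integer(n_nodes), N_endog = as.integer(N_endog),
    N_exog = as.integer(N_exog),
    k_a_endog = k_a_endog, k_d_endog = k_d_endog,
    k_a_exog = k_a_exog, k_d_exog = k_d_exog,
    k_join = k_join, k_break = k_break, E_bond = E_bond,
    N_max = N_max, neighbor_radius = neighbor_radius,
    model_variant = model_variant,
    exog_species = if (model_variant %in% c("weak_binding_ML", "capping_ML"))
      3L else 2L,
    capping = model_variant == "capping_ML",
    n_steps = as.integer(n_steps), n_iterations = as.integer(n_iterations),
    snapshot_every = as.integer(snapshot_every), burnin_frac = burnin_frac,
    n_surfaces = as.integer(n_surfaces), diameter_scale = diameter_scale,
    seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

# parameter block handed to the C++ core
.core_params <- function(p) {
  list(k_a_endog = p$k_a_endog, k_d_endog = p$k_d_endog,
       k_a_exog = p$k_a_exog, k_d_exog = p$k_d_exog,
       k_join = p$k_join, k_break = p$k_break, E_bond = p$E_bond,
       neighbor_radius2 = p$neighbor_radius^2,
       N_max = if (is.infinite(p$N_max)) -1L else as.integer(p$N_max),
       n_surfaces = p$n_surfaces, capping = isTRUE(p$capping))
}

#' Initialize a self-avoiding lattice polymer
#'
#' Starts from a straight rod and applies a pivot-move burn-in
#' (`10 * n_nodes` accepted moves) so the returned configuration is a valid
#' self-avoiding chain with unit bonds.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param seed random seed.
#' @return Integer matrix (`n_nodes` x 3) of lattice coordinates, class
#'   `lattice_polymer`.
#' @export
init_polymer <- function(n_nodes, seed = 1L) {
  if (!is.numeric(n_nodes) || n_nodes < 1)
    stop("n_nodes must be >= 1")
  set.seed(seed)
  coords <- cpp_init_polymer(as.integer(n_nodes), 10L * as.integer(n_nodes))
  colnames(coords) <- c("x", "y", "z")
  class(coords) <- c("lattice_polymer", class(coords))
  coords
}

#' Draw per-node binding affinities
#'
#' Each chromatin node gets an affinity drawn uniformly on \[0, 1\], fixed
#' for the whole run; the affinity multiplies the mass-action association
#' probability at that node.
#'
#' @param n_nodes number of nodes.
#' @param seed random seed.
#' @return Numeric vector of affinities in \[0, 1\].
#' @export
assign_affinities <- function(n_nodes, seed = 1L) {
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  set.seed(seed)
  stats::runif(n_nodes)
}

#' Create a fresh simulation state
#'
#' Builds the full mutable state (polymer coordinates, node affinities and
#' an all-free binder pool) used by [binding_step()], [bridging_step()] and
#' the move proposal functions.
#'
#' @param params a [sim_params()] object.
#' @param seed random seed for polymer burn-in and affinities.
#' @return A list of class `sim_state` with elements `coords`, `affinity`,
#'   `species` (1 = endogenous Ph, 2 = exogenous Ph, 3 = Ph-ML), `node`
#'   (0 = free, otherwise 1-based node index), `nbonds`, `capped`, `bonds`
#'   (two-column matrix of binder indices) and `n_capped`.
#' @export
new_sim_state <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  coords <- cpp_init_polymer(params$n_nodes, 10L * params$n_nodes)
  nb <- params$N_endog + params$N_exog
  species <- c(rep(1L, params$N_endog), rep(params$exog_species,
                                            params$N_exog))
  st <- list(coords = coords, affinity = stats::runif(params$n_nodes),
             species = species, node = rep(0L, nb),
             nbonds = rep(0L, nb), capped = rep(0L, nb),
             bonds = matrix(integer(0), 0, 2), n_capped = 0L)
  class(st) <- "sim_state"
  st
}

#' Remaining free interaction surfaces per binder
#'
#' A molecule's free surfaces are its total surfaces minus bridge bonds held
#' minus caps received; capped or fully bonded molecules cannot form new
#' bridges.
#'
#' @param state a `sim_state`.
#' @param params the matching [sim_params()].
#' @return Integer vector, one entry per binder.
#' @export
surfaces_free <- function(state, params) {
  pmax(0L, params$n_surfaces - state$nbonds - state$capped)
}

#' Propose a pivot move
#'
#' Picks (or accepts as arguments) a pivot node and one of the 47
#' non-identity signed-permutation lattice symmetries, rotates the chain arm
#' beyond the pivot, and flags the proposal invalid if any two nodes would
#' collide. Nodes `1..pivot_index` are never moved.
#'
#' @param polymer coordinate matrix (n x 3).
#' @param pivot_index 1-based pivot node; random if `NULL`.
#' @param sym_index symmetry index 1..47 (0 forces the identity); random if
#'   `NULL`.
#' @param seed optional seed for the random choices.
#' @return List with `coords` (proposed matrix), `valid` (logical),
#'   `pivot_index`, `sym_index`.
#' @export
propose_pivot <- function(polymer, pivot_index = NULL, sym_index = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(polymer)
  if (is.null(pivot_index)) pivot_index <- sample.int(max(n - 1L, 1L), 1L)
  if (is.null(sym_index)) sym_index <- sample.int(47L, 1L)
  res <- cpp_propose_pivot(unclass_matrix(polymer),
                           as.integer(pivot_index) - 1L,
                           as.integer(sym_index))
  res$pivot_index <- pivot_index
  res$sym_index <- sym_index
  res
}

#' Propose a single-site (bond-fluctuation style) move
#'
#' Displaces one node by one lattice unit; the proposal is valid only if
#' both chain bonds at that node keep squared length in \{1, 2\} and the
#' target site is unoccupied.
#'
#' @param polymer coordinate matrix.
#' @param node_index 1-based node to displace.
#' @param direction 1..6 (+x, -x, +y, -y, +z, -z); random if `NULL`.
#' @param seed optional seed.
#' @return List with `coords`, `valid`, `direction`.
#' @export
propose_local_move <- function(polymer, node_index, direction = NULL,
                               seed = NULL) {
  n <- nrow(polymer)
  if (node_index < 1 || node_index > n)
    stop("node_index out of range")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(direction)) direction <- sample.int(6L, 1L)
  res <- cpp_propose_local(unclass_matrix(polymer),
                           as.integer(node_index) - 1L,
                           as.integer(direction) - 1L)
  res$direction <- direction
  res
}

unclass_matrix <- function(m) {
  class(m) <- NULL
  attr(m, "dimnames") <- NULL
  m
}

#' Energy change of a proposed polymer move
#'
#' A move costs `E_bond` for every existing binder-binder bridge bond whose
#' two nodes would end up farther apart than the neighbour radius (those
#' bonds break if the move is accepted). Moves that break no bond are free.
#'
#' @param state a `sim_state`.
#' @param proposal proposed coordinate matrix (e.g. from
#'   [propose_pivot()]`$coords`).
#' @param params the matching [sim_params()].
#' @return Energy difference in kT, with attribute `broken` holding the row
#'   indices of the bonds that would break.
#' @export
move_energy_delta <- function(state, proposal, params) {
  broken <- cpp_broken_bonds(unclass_matrix(proposal), unclass(state),
                             params$neighbor_radius^2)
  dE <- params$E_bond * length(broken)
  attr(dE, "broken") <- broken
  dE
}

#' Metropolis acceptance
#'
#' Accepts a move with probability `min(1, exp(-delta_energy))`, energies in
#' units of kT.
#'
#' @param delta_energy energy change.
#' @param seed optional seed.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_energy, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  delta_energy <- as.numeric(delta_energy)
  delta_energy <= 0 || stats::runif(1) < exp(-delta_energy)
}

#' One mass-action binding/unbinding sweep
#'
#' Every bound molecule first dissociates with probability `k_d` of its
#' species (losing its bridge bonds and any cap). Then each node is visited
#' once per species: a free molecule associates with probability
#' `k_a * A_node * (free pool fraction)` provided the node is below `N_max`
#' (limited-spreading variants) and, in the capping variant, the resident
#' cluster still has at least one uncapped Ph. In the capping variant each
#' Ph-ML that joins an existing cluster caps one uncapped resident Ph chosen
#' uniformly at random.
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @param seed optional seed.
#' @return Updated `sim_state`.
#' @export
binding_step <- function(state, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_binding_step(unclass(state), .core_params(params))
  class(st) <- "sim_state"
  st
}

#' One bridging sweep
#'
#' Existing bridge bonds break with probability `k_break`. Then, for every
#' pair of bound molecules with free surfaces sitting at distinct nodes
#' within the neighbour radius, a bond forms with probability `k_join`.
#' Node saturation does not block bridging; capped molecules (no free
#' surfaces) form no new bonds.
#'
#' @inheritParams binding_step
#' @return Updated `sim_state`.
#' @export
bridging_step <- function(state, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_bridging_step(unclass(state), .core_params(params))
  class(st) <- "sim_state"
  st
}

#' Partition bound molecules into clusters
#'
#' A cluster is a maximal set of bound molecules connected by co-occupancy
#' of a node or by bridge bonds.
#'
#' @param state a `sim_state`.
#' @return Integer vector of cluster labels per binder (`NA` for free
#'   molecules); cluster sizes are `table()` of the labels.
#' @export
cluster_census <- function(state) {
  cpp_cluster_census(unclass(state))
}

#' Cluster diameter from molecule count
#'
#' Molecule number is assumed to scale with the third power of cluster
#' diameter, so `diameter = scale * n^(1/3)`.
#'
#' @param n_molecules molecule count(s), >= 1.
#' @param scale length per unit cube-root molecule (default 30).
#' @return Numeric diameter(s), same units as `scale`.
#' @export
diameter_from_size <- function(n_molecules, scale = 30) {
  if (any(n_molecules < 1)) stop("cluster size must be >= 1")
  scale * n_molecules^(1 / 3)
}

# molecule-weighted median cluster size: each cluster weighted by the
# molecules it holds, mirroring the localization-weighted size statistics
# used for imaging data; single molecules (sub-resolution objects) are
# excluded, mirroring the imaging convention of dropping single-bin calls
.weighted_median_size <- function(sizes, min_size = 2) {
  s <- sort(sizes[sizes >= min_size])
  if (length(s) == 0) return(NA_integer_)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

.contact_scalar <- function(contact_pairs, n_snapshots, ever_occupied) {
  n_occ <- sum(ever_occupied)
  n_pairs <- n_occ * (n_occ - 1) / 2
  if (n_pairs == 0) return(0)
  sum(contact_pairs[, "n_snapshots"] / n_snapshots) / n_pairs
}

#' Run the full simulation
#'
#' Runs `n_iterations` independent replicates of `n_steps` Monte-Carlo
#' steps. Each step attempts a pivot move (falling back to a single-site
#' move on geometric rejection; bond-breaking moves pass through Metropolis
#' acceptance), then a binding sweep, then a bridging sweep. Snapshots are
#' recorded every `snapshot_every` steps after the burn-in fraction of the
#' run.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `sim_observables`: a list with `summary`
#'   (one row per iteration: cluster counts with and without single
#'   molecules, median cluster size/diameter, molecule-weighted median
#'   diameter over clusters of two or more molecules, bridge contact
#'   frequency over ever-occupied node pairs, per-snapshot contact
#'   frequency among cluster sites, bridged node pairs per snapshot, mean
#'   bound counts, RMS end-to-end distance), `cluster_sizes` (per-iteration
#'   list of snapshot size vectors), `contacts` (per-iteration node-pair
#'   contact counts), `ever_occupied`, `n_snapshots` and `params`.
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  iters <- vector("list", params$n_iterations)
  for (i in seq_len(params$n_iterations)) {
    set.seed(params$seed + i)
    iters[[i]] <- cpp_run_iteration(
      params$n_nodes, params$N_endog, params$N_exog, params$exog_species,
      .core_params(params), params$n_steps, params$snapshot_every,
      params$burnin_frac, 10L * params$n_nodes)
  }
  summ <- do.call(rbind, lapply(seq_along(iters), function(i) {
    it <- iters[[i]]
    sizes <- unlist(it$cluster_sizes)
    data.frame(
      iteration = i,
      n_clusters = mean(vapply(it$cluster_sizes, length, integer(1))),
      n_clusters_multi = mean(vapply(it$cluster_sizes, function(s)
        sum(s >= 2), integer(1))),
      median_cluster_size = if (length(sizes)) stats::median(sizes) else 0,
      median_diameter = if (length(sizes))
        stats::median(diameter_from_size(sizes, params$diameter_scale))
        else 0,
      weighted_median_diameter = {
        wms <- .weighted_median_size(sizes)
        if (is.na(wms)) 0 else diameter_from_size(wms,
                                                  params$diameter_scale)
      },
      contact_frequency = .contact_scalar(it$contact_pairs, it$n_snapshots,
                                          it$ever_occupied),
      cluster_contact_frequency = if (length(it$cluster_contact_freq))
        mean(it$cluster_contact_freq) else NA_real_,
      bridged_pairs = if (it$n_snapshots > 0)
        sum(it$contact_pairs[, "n_snapshots"]) / it$n_snapshots else 0,
      mean_bound_endog = mean(it$bound_endog),
      mean_bound_exog = mean(it$bound_exog),
      rms_end_to_end = sqrt(mean(it$end_to_end_sq)))
  }))
  obs <- list(summary = summ,
              cluster_sizes = lapply(iters, `[[`, "cluster_sizes"),
              contacts = lapply(iters, `[[`, "contact_pairs"),
              ever_occupied = lapply(iters, `[[`, "ever_occupied"),
              n_snapshots = vapply(iters, `[[`, integer(1), "n_snapshots"),
              params = params)
  class(obs) <- "sim_observables"
  obs
}

#' @export
print.sim_observables <- function(x, ...) {
  cat(sprintf("strings-and-binders simulation: %d nodes, variant '%s'\n",
              x$params$n_nodes, x$params$model_variant))
  cat(sprintf("%d iterations x %d steps; N_endog=%d N_exog=%d\n",
              x$params$n_iterations, x$params$n_steps,
              x$params$N_endog, x$params$N_exog))
  print(summary(x$summary[, c("n_clusters", "median_diameter",
                              "contact_frequency")]))
  invisible(x)
}

#' Bridge contact frequency among polymer nodes
#'
#' For each unordered node pair, the fraction of snapshots in which at least
#' one bridge bond linked molecules bound at the two nodes. The scalar
#' summary averages these fractions over all pairs of nodes that were each
#' occupied in at least one snapshot (never-bound nodes would otherwise
#' dilute the mean).
#'
#' @param observables a `sim_observables` from [run_simulation()].
#' @return List with `pairs` (data frame `node_i`, `node_j`, `frequency`
#'   pooled over iterations) and `scalar` (mean over eligible pairs).
#' @export
contact_frequency <- function(observables) {
  stopifnot(inherits(observables, "sim_observables"))
  if (sum(observables$n_snapshots) == 0)
    stop("empty trajectory: no snapshots recorded")
  total_snap <- sum(observables$n_snapshots)
  pool <- list()
  for (i in seq_along(observables$contacts)) {
    cm <- observables$contacts[[i]]
    if (nrow(cm)) pool[[length(pool) + 1L]] <- cm
  }
  if (length(pool)) {
    all <- do.call(rbind, pool)
    df <- stats::aggregate(n_snapshots ~ node_i + node_j, data = as.data.frame(all),
                           FUN = sum)
    df$frequency <- df$n_snapshots / total_snap
    df <- df[order(df$node_i, df$node_j), c("node_i", "node_j", "frequency")]
  } else {
    df <- data.frame(node_i = integer(0), node_j = integer(0),
                     frequency = numeric(0))
  }
  ever <- Reduce(`|`, observables$ever_occupied)
  n_occ <- sum(ever)
  n_pairs <- n_occ * (n_occ - 1) / 2
  scalar <- if (n_pairs == 0) 0 else sum(df$frequency) / n_pairs
  list(pairs = df, scalar = scalar)
}

#' Sweep exogenous binder concentration for one model variant
#'
#' Runs [run_simulation()] at each value of `N_exog_grid` and returns a tidy
#' per-iteration summary, the raw material for the concentration-response
#' curves (cluster number, median cluster diameter, bridge contact
#' frequency) that distinguish the weak-binding, capping and
#' limited/unlimited-spreading mechanisms.
#'
#' @param model_variant variant name, see [sim_params()].
#' @param N_exog_grid integer vector of exogenous molecule counts.
#' @param ... overrides passed to [sim_params()] (e.g. `n_nodes`,
#'   `n_iterations`, `n_steps`, `seed`).
#' @return Data frame with columns `variant`, `N_exog`, `iteration`,
#'   `n_clusters`, `median_cluster_size`, `median_diameter`,
#'   `contact_frequency`.
#' @export
run_variant_sweep <- function(model_variant, N_exog_grid, ...) {
  out <- lapply(N_exog_grid, function(nx) {
    p <- sim_params(model_variant = model_variant, N_exog = nx, ...)
    obs <- run_simulation(p)
    cbind(variant = model_variant, N_exog = nx,
          obs$summary[, c("iteration", "n_clusters", "n_clusters_multi",
                          "median_cluster_size", "median_diameter",
                          "weighted_median_diameter", "contact_frequency",
                          "cluster_contact_frequency", "bridged_pairs")])
  })
  do.call(rbind, out)
}

#' Run a mutant-mechanism or overexpression simulation study
#'
#' Reproduces the two concentration-response experiments that discriminate
#' the clustering mechanisms:
#' \describe{
#'   \item{`"ML"`}{weak-binding versus oligomer-capping Ph-ML, swept over
#'     exogenous Ph-ML counts \{0, 10, 30, 90, 270\} against 30 endogenous
#'     Ph molecules. The capping model shows a non-monotone weighted median
#'     cluster diameter (rise at sub-stoichiometric Ph-ML, then sharp fall)
#'     and abolishes cluster-site contacts; the weak-binding model rises to
#'     the spreading cap and stays there.}
#'   \item{`"WT"`}{limited versus unlimited spreading of extra wild-type
#'     Ph, swept over \{0, 30, 60, 150, 400\} against 100 endogenous
#'     molecules. Limited spreading multiplies cluster sites and long-range
#'     contacts with modest size growth; unlimited spreading condenses mass
#'     into few large clusters with far smaller contact gains.}
#' }
#' Default sizes (200 nodes, 20 iterations, 4000 or 8000 steps) keep a full
#' study within a few minutes on one core.
#'
#' @param study `"ML"` or `"WT"`.
#' @param seed base seed.
#' @param n_iterations iterations per grid point.
#' @param n_nodes polymer size.
#' @param ... further overrides for [sim_params()].
#' @return Tidy data frame as from [run_variant_sweep()], both variants
#'   stacked.
#' @export
mechanism_study <- function(study = c("ML", "WT"), seed = 1L,
                            n_iterations = 20, n_nodes = 200, ...) {
  study <- match.arg(study)
  if (study == "ML") {
    variants <- c("weak_binding_ML", "capping_ML")
    N_endog <- 30
    grid <- c(0, 10, 30, 90, 270)
    n_steps <- 4000
  } else {
    variants <- c("wt_limited", "wt_unlimited")
    N_endog <- 100
    grid <- c(0, 30, 60, 150, 400)
    n_steps <- 8000
  }
  do.call(rbind, lapply(variants, function(v)
    run_variant_sweep(v, grid, n_nodes = n_nodes, N_endog = N_endog,
                      n_steps = n_steps, n_iterations = n_iterations,
                      snapshot_every = 100, seed = seed, ...)))
}
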