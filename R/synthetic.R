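#' Configuration for the synthetic world
#'
#' Defaults emulate the aging-cohort structure the evaluation repertoire was
#' designed around: 28 inbred strains with roughly 57 mice each (~1,600
#' mice), a mean of about 13 diagnoses per mouse, and a small fraction of
#' mice that stay healthy.  Ontology shape parameters describe scaled-down
#' toy ontologies: real anatomy/pathology ontologies have thousands of
#' classes at taxonomy depth 8-9; the toys keep a comparable branching
#' factor at desk scale.
#'
#' @param n_strains number of inbred strains.
#' @param mice_per_strain mice per strain.
#' @param healthy_fraction fraction of each strain's mice left without any
#'   diagnosis (they carry the root annotation downstream).
#' @param diagnoses_per_mouse mean of the per-mouse Poisson diagnosis count.
#' @param anatomy_size,pathology_size class counts of the toy ontologies
#'   (excluding the root).
#' @param anatomy_depth,pathology_depth taxonomy depth of the toys.
#' @param part_of_density expected number of `part_of` edges per anatomy
#'   class (edges run from deeper to shallower non-ancestral classes).
#' @param vocab_size number of distinct (anatomy leaf, pathology leaf) pairs
#'   in the global diagnosis vocabulary.
#' @param concentration Dirichlet concentration of the strain propensity
#'   distributions over the vocabulary; low values make strains strongly
#'   pair-specific, large values drive all strains toward one shared
#'   propensity (and strain signal toward chance).
#' @param combination_only if `TRUE`, strains share identical anatomy and
#'   pathology marginals and differ only in how anatomy and pathology are
#'   paired: strain s pairs anatomy leaf i with pathology leaf
#'   `(i + s) mod L`, drawn uniformly — the scenario where only compound
#'   ontologies can see the strain signal.
#' @param seed single integer seed; all stochastic steps derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_strains = 28L, mice_per_strain = 57L,
                       healthy_fraction = 0.05, diagnoses_per_mouse = 13,
                       anatomy_size = 60L, pathology_size = 40L,
                       anatomy_depth = 5L, pathology_depth = 4L,
                       part_of_density = 0.1, vocab_size = 150L,
                       concentration = 1, combination_only = FALSE,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              mice_per_strain = as.integer(mice_per_strain),
              healthy_fraction = healthy_fraction,
              diagnoses_per_mouse = diagnoses_per_mouse,
              anatomy_size = as.integer(anatomy_size),
              pathology_size = as.integer(pathology_size),
              anatomy_depth = as.integer(anatomy_depth),
              pathology_depth = as.integer(pathology_depth),
              part_of_density = part_of_density,
              vocab_size = as.integer(vocab_size),
              concentration = concentration,
              combination_only = isTRUE(combination_only),
              seed = as.integer(seed))
  counts <- c("n_strains", "mice_per_strain", "anatomy_size",
              "pathology_size", "anatomy_depth", "pathology_depth",
              "vocab_size")
  if (any(unlist(cfg[counts]) <= 0L)) stop("all counts must be positive")
  if (cfg$healthy_fraction < 0 || cfg$healthy_fraction > 1) {
    stop("healthy_fraction must lie in [0, 1]")
  }
  if (cfg$diagnoses_per_mouse < 0) stop("diagnoses_per_mouse must be >= 0")
  if (cfg$concentration <= 0) stop("concentration must be positive")
  structure(cfg, class = "sim_config")
}

#' Generate a pair of toy ontologies
#'
#' Random rooted DAGs with the requested size and depth.  Classes are
#' assigned levels 1..depth (at least one per level); each takes one parent
#' from the level above, and a tenth of them take a second parent from any
#' shallower level, so the taxonomy is a genuine DAG rather than a tree.
#' The anatomy toy additionally receives `part_of` edges, drawn from deeper
#' to strictly shallower non-ancestral classes at the configured density
#' (acyclic by construction).  Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return List with elements `anatomy` and `pathology`, both
#'   [ontology_graph()]s.
#' @export
generate_toy_ontologies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  anatomy <- random_dag("ANAT", config$anatomy_size, config$anatomy_depth,
                        part_of_density = config$part_of_density)
  pathology <- random_dag("PATH", config$pathology_size,
                          config$pathology_depth, part_of_density = 0)
  list(anatomy = anatomy, pathology = pathology)
}

random_dag <- function(prefix, size, depth, part_of_density = 0,
                       multi_parent_prob = 0.1) {
  if (size < depth) stop("infeasible shape: size ", size, " < depth ", depth)
  root <- sprintf("%s:0000", prefix)
  ids <- sprintf("%s:%04d", prefix, seq_len(size))
  # levels 1..depth, each guaranteed non-empty
  level <- c(seq_len(depth),
             if (size > depth) sample(depth, size - depth, replace = TRUE))
  level <- sample(level)                      # shuffle assignment to IDs
  by_level <- split(ids, level)
  parent_pool <- c(list(`0` = root), by_level)
  child <- character(); parent <- character()
  for (l in seq_len(depth)) {
    for (cl in by_level[[as.character(l)]]) {
      pool <- parent_pool[[as.character(l - 1L)]]
      child <- c(child, cl)
      parent <- c(parent, pool[sample.int(length(pool), 1L)])
      if (stats::runif(1) < multi_parent_prob && l > 1L) {
        l2 <- sample.int(l - 1L, 1L)
        pool2 <- parent_pool[[as.character(l2)]]
        p2 <- pool2[sample.int(length(pool2), 1L)]
        child <- c(child, cl); parent <- c(parent, p2)
      }
    }
  }
  po <- NULL
  n_po <- round(part_of_density * size)
  if (n_po > 0) {
    g_tmp <- ontology_graph(c(root, ids), is_a = cbind(child, parent),
                            root = root, check = FALSE)
    deep <- ids[level[match(ids, ids)] > 1L]
    po_child <- character(); po_parent <- character()
    tries <- 0L
    while (length(po_child) < n_po && tries < 50L * n_po) {
      tries <- tries + 1L
      x <- deep[sample.int(length(deep), 1L)]
      lx <- level[match(x, ids)]
      shallower <- ids[level < lx]
      if (!length(shallower)) next
      y <- shallower[sample.int(length(shallower), 1L)]
      if (y %in% ancestors(g_tmp, x, "is_a", reflexive = TRUE)) next
      if (any(po_child == x & po_parent == y)) next
      po_child <- c(po_child, x); po_parent <- c(po_parent, y)
    }
    if (length(po_child)) po <- cbind(child = po_child, parent = po_parent)
  }
  labels <- setNames(c(sprintf("%s root", tolower(prefix)),
                       sprintf("%s class %d", tolower(prefix), seq_len(size))),
                     c(root, ids))
  ontology_graph(c(root, ids), labels, is_a = cbind(child, parent),
                 part_of = po, root = root)
}

#' Simulate a strain-structured cohort
#'
#' Draws a global vocabulary of (anatomy leaf, pathology leaf) diagnosis
#' pairs, gives each strain its own propensity distribution over that
#' vocabulary (Dirichlet with the configured concentration), and samples
#' each mouse's diagnoses: a Poisson count of draws from its strain's
#' propensities, with a `healthy_fraction` of each strain's mice forced to
#' zero diagnoses.  Sex and study group are assigned round-robin within
#' strain, so strata stay balanced.
#'
#' In `combination_only` mode the vocabulary is the union of the per-strain
#' pairings of L anatomy leaves with L pathology leaves under cyclic shifts;
#' every strain draws uniformly over its own L pairs, which fixes identical
#' uniform anatomy and pathology marginals across strains while the
#' (anatomy, pathology) pairing carries all the strain signal.
#'
#' @param config a [sim_config()].
#' @param anatomy,pathology toy or loaded [ontology_graph()]s.
#' @return A [cohort()]; the config is attached as attribute `sim_config`.
#' @export
simulate_cohort <- function(config, anatomy, pathology) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  a_leaves <- sort(leaves(anatomy))
  p_leaves <- sort(leaves(pathology))
  if (!length(a_leaves) || !length(p_leaves)) stop("empty vocabulary")

  if (config$combination_only) {
    L <- min(length(a_leaves), length(p_leaves))
    if (config$n_strains > L) {
      warning("more strains than leaves: cyclic pairings repeat across strains")
    }
    strain_pairs <- lapply(seq_len(config$n_strains), function(s) {
      shift <- (s - 1L) %% L
      data.frame(anatomy_id = a_leaves[seq_len(L)],
                 pathology_id = p_leaves[(seq_len(L) - 1L + shift) %% L + 1L],
                 stringsAsFactors = FALSE)
    })
    strain_prop <- lapply(strain_pairs, function(p) rep(1 / nrow(p), nrow(p)))
  } else {
    grid_n <- length(a_leaves) * length(p_leaves)
    v <- min(config$vocab_size, grid_n)
    pick <- sample.int(grid_n, v)
    vocab <- data.frame(
      anatomy_id = a_leaves[(pick - 1L) %% length(a_leaves) + 1L],
      pathology_id = p_leaves[(pick - 1L) %/% length(a_leaves) + 1L],
      stringsAsFactors = FALSE)
    strain_pairs <- rep(list(vocab), config$n_strains)
    strain_prop <- lapply(seq_len(config$n_strains), function(s) {
      w <- stats::rgamma(nrow(vocab), shape = config$concentration)
      if (sum(w) == 0) w <- rep(1, length(w))
      w / sum(w)
    })
  }

  sexes <- c("F", "M")
  groups <- c("12m", "20m", "LONG")
  mice <- list(); recs <- list()
  idx <- 0L
  for (s in seq_len(config$n_strains)) {
    strain <- sprintf("STRAIN%02d", s)
    n <- config$mice_per_strain
    m_ids <- sprintf("m%05d", idx + seq_len(n))
    idx <- idx + n
    healthy <- rep(FALSE, n)
    n_healthy <- round(config$healthy_fraction * n)
    if (n_healthy > 0) healthy[sample.int(n, n_healthy)] <- TRUE
    counts <- stats::rpois(n, config$diagnoses_per_mouse)
    counts[healthy] <- 0L
    mice[[s]] <- data.frame(
      mouse_id = m_ids, strain = strain,
      sex = sexes[(seq_len(n) - 1L) %% 2L + 1L],
      group = groups[((seq_len(n) - 1L) %/% 2L) %% 3L + 1L],
      stringsAsFactors = FALSE)
    pairs <- strain_pairs[[s]]; prop <- strain_prop[[s]]
    draw <- unlist(lapply(seq_len(n), function(i) {
      if (counts[i] == 0L) return(integer())
      sample.int(nrow(pairs), counts[i], replace = TRUE, prob = prop)
    }))
    if (length(draw)) {
      recs[[s]] <- data.frame(
        mouse_id = rep(m_ids, counts),
        anatomy_id = pairs$anatomy_id[draw],
        pathology_id = pairs$pathology_id[draw],
        stringsAsFactors = FALSE)
    }
  }
  out <- cohort(do.call(rbind, mice),
                if (length(recs)) do.call(rbind, recs) else
                  data.frame(mouse_id = character(),
                             anatomy_id = character(),
                             pathology_id = character(),
                             stringsAsFactors = FALSE))
  attr(out, "sim_config") <- config
  out
}
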