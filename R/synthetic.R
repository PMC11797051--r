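#' Simulate a Yule (pure-birth) phylogeny
#'
#' Lineages split at rate `birth_rate` until `n_taxa` tips exist; branch
#' lengths accumulate the exponential waiting times (via `ape::rphylo` with
#' zero extinction). Tips are relabeled deterministically `ASV_001 ...`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate (default 1).
#' @param seed optional RNG seed.
#' @return a `phylo` tree with branch lengths.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("ASV_%03d", seq_len(n_taxa))
  tree
}

#' Evolve a continuous niche trait by (early-burst) Brownian motion
#'
#' Root value 0; along each branch the trait changes by a normal increment
#' whose variance is `bm_rate` times the branch length, so closely related
#' tips have similar traits — the phylogenetic signal assumed by
#' nearest-taxon null models. With `eb_rate > 0` the instantaneous rate
#' declines as exp(-eb_rate * t) with time t from the root (the early-burst
#' model of niche conservatism): trait divergence concentrates in deep
#' branches, making clades — not single tips — the units an environmental
#' filter selects. `eb_rate = 0` is exact Brownian motion.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param bm_rate trait variance accumulated per unit branch length (at the
#'   root, when `eb_rate > 0`).
#' @param seed optional RNG seed.
#' @param eb_rate exponential decay rate of the Brownian rate with time
#'   from the root (default 0 = rate constant).
#' @return named numeric vector of per-tip trait values.
#' @export
evolve_trait_bm <- function(tree, bm_rate, seed = NULL, eb_rate = 0) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  stopifnot(bm_rate >= 0, eb_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  if (bm_rate == 0)
    return(stats::setNames(rep(0, ntip), tree$tip.label))
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  depth <- ape::node.depth.edgelength(tree)  # time from root per node
  trait <- numeric(ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    t0 <- depth[par]
    t1 <- depth[ch]
    v <- if (eb_rate > 0) {
      bm_rate * (exp(-eb_rate * t0) - exp(-eb_rate * t1)) / eb_rate
    } else {
      bm_rate * (t1 - t0)
    }
    trait[ch] <- trait[par] + stats::rnorm(1, 0, sqrt(v))
  }
  stats::setNames(trait[seq_len(ntip)], tree$tip.label)
}

#' Expand backbone tips into terminal microdiversity clusters
#'
#' 16S ASV (zOTU) tables resolve clusters of near-identical sequence
#' variants within each biological population. This helper emulates that
#' two-scale structure: each tip of a backbone (species-level) tree is
#' replaced by a star-shaped cluster of `sizes[i]` tips whose pendant edges
#' are short (`cluster_depth` times a uniform factor) relative to the
#' backbone edges. Tips are labelled `ASV_001 ...` in cluster-major order.
#'
#' @param backbone a `phylo` tree (one tip per species/population).
#' @param sizes integer vector of cluster sizes, one per backbone tip.
#' @param cluster_depth scale of the within-cluster pendant edges, in the
#'   backbone's branch-length units.
#' @param seed optional RNG seed for the pendant-edge jitter.
#' @return a `phylo` tree with `sum(sizes)` tips.
#' @export
expand_microdiversity <- function(backbone, sizes, cluster_depth,
                                  seed = NULL) {
  stopifnot(length(sizes) == length(backbone$tip.label), all(sizes >= 1),
            cluster_depth >= 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- backbone
  tree$tip.label <- sprintf(".bb%d", seq_along(tree$tip.label))
  offset <- 0L
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    labels <- sprintf("ASV_%03d", offset + seq_len(k))
    offset <- offset + k
    tip <- which(tree$tip.label == sprintf(".bb%d", i))
    if (k == 1L) {
      tree$tip.label[tip] <- labels
      next
    }
    star <- ape::stree(k, "star", tip.label = labels)
    star$edge.length <- cluster_depth * stats::runif(k, 0.5, 1.5)
    star$root.edge <- 0
    tree <- ape::bind.tree(tree, star, where = tip)
  }
  tree
}

## Dirichlet perturbation with concentration theta (Inf = none)
dirichlet_drift <- function(p, theta) {
  if (!is.finite(theta)) return(p)
  g <- stats::rgamma(length(p), shape = theta * p)
  if (sum(g) > 0) g / sum(g) else p
}

## two-stage founder drift: clusters (populations) first, then the ASV
## strains within each cluster; selection fixes which clusters carry
## weight, founder drift decides which of them establish and which strain
## variant dominates in this flask
founder_weights <- function(p, cluster, cluster_theta, strain_theta,
                            strain_mix = 0.15) {
  ctot <- tapply(p, cluster, sum)
  cdrift <- dirichlet_drift(as.vector(ctot), cluster_theta)
  names(cdrift) <- names(ctot)
  within <- p / ave(p, cluster, FUN = sum)
  within[!is.finite(within)] <- 0
  g <- stats::rgamma(length(p), shape = strain_theta * within)
  gsum <- ave(g, cluster, FUN = sum)
  wdrift <- ifelse(gsum > 0, g / gsum, within)
  # minor strains of an established population stay present at low level:
  # which strain dominates is a founder event, presence is not
  wmix <- (1 - strain_mix) * wdrift + strain_mix * within
  w <- wmix * cdrift[as.character(cluster)]
  if (sum(w) == 0) p else w / sum(w)
}

## Gaussian-filter selection weights over the metacommunity
selection_weights <- function(metacommunity, traits, env, sigma) {
  w <- if (is.finite(sigma)) {
    metacommunity * exp(-(traits - env)^2 / (2 * sigma^2))
  } else {
    metacommunity
  }
  if (sum(w) == 0)
    stop("all sampling weights are zero: no taxon trait near env = ", env,
         "; increase sigma")
  w / sum(w)
}

#' Assemble one community sample under selection, dispersal and drift
#'
#' Sampling weights combine the metacommunity with a Gaussian environmental
#' filter on the niche trait, p_t proportional to
#' m_t * exp(-(trait_t - env)^2 / (2 sigma^2)); `sigma = Inf` removes
#' selection (neutral limit, p_t = m_t). A mass-effect dispersal component
#' mixes a fraction `dispersal` of a source community (by default the
#' unfiltered metacommunity) into the weights; ecological drift — a
#' Dirichlet perturbation with concentration `theta` (small `theta` =
#' strong drift, `theta = Inf` = none) — then acts on residents and
#' established immigrants alike, leaving each sample a sparse random
#' subset of the phylogenetically broad immigrant tail, as in real
#' communities. Finally `depth` reads are drawn multinomially.
#'
#' @param metacommunity relative abundances summing to 1, named by taxon.
#' @param traits named per-taxon niche trait values.
#' @param env environmental optimum (trait units).
#' @param sigma selection width (trait units); `Inf` for neutral.
#' @param depth reads to draw (>= 1).
#' @param seed optional RNG seed.
#' @param theta drift concentration; default `Inf` (no drift).
#' @param dispersal mass-effect fraction of the source community mixed into
#'   the weights before drift (default 0).
#' @param dispersal_source relative abundances of the immigration source
#'   (default: `metacommunity` itself).
#' @return named integer count vector.
#' @export
assemble_sample <- function(metacommunity, traits, env, sigma, depth,
                            seed = NULL, theta = Inf, dispersal = 0,
                            dispersal_source = metacommunity) {
  stopifnot(depth >= 1, sigma > 0, theta > 0,
            dispersal >= 0, dispersal <= 1)
  if (abs(sum(metacommunity) - 1) > 1e-6)
    stop("metacommunity abundances must sum to 1")
  if (is.null(names(metacommunity))) stop("metacommunity must be named")
  traits <- traits[names(metacommunity)]
  if (anyNA(traits)) stop("traits missing for some metacommunity taxa")
  if (!is.null(seed)) set.seed(seed)
  p <- selection_weights(metacommunity, traits, env, sigma)
  if (dispersal > 0)
    p <- (1 - dispersal) * p + dispersal *
      dispersal_source / sum(dispersal_source)
  p <- dirichlet_drift(p, theta)
  counts <- stats::rmultinom(1, size = depth, prob = p)[, 1]
  stats::setNames(as.integer(counts), names(metacommunity))
}

#' Parameterize a synthetic rearing experiment
#'
#' Encodes the full study design emulated by [generate_experiment()]: a
#' 2 x 2 factorial (water treatment x host strain) with replicate flasks,
#' several individual gut samples per flask, one rearing-water sample per
#' flask, repeated added-water samples, and negative controls carrying
#' sparse contamination. Assembly follows one of three processes:
#' `homogeneous_selection` (one shared environmental optimum),
#' `heterogeneous_selection` (divergent optima between water treatments),
#' or `neutral` (no trait filter).
#'
#' @param n_taxa metacommunity size in ASVs (default 200).
#' @param n_species backbone (species-level) tree size; ASVs are spread
#'   over the species as equal-sized microdiversity clusters (default 50,
#'   i.e. 4 strain variants per species at the default `n_taxa`).
#' @param cluster_depth pendant-edge scale of the within-species ASV
#'   clusters, in backbone branch-length units (default 0.02; see
#'   [expand_microdiversity()]).
#' @param birth_rate Yule speciation rate (default 1).
#' @param bm_rate Brownian trait variance per unit branch length at the
#'   root (default 1).
#' @param eb_rate early-burst decay of the trait rate with time from the
#'   root (default 1, conserved niches; 0 = plain Brownian motion; see
#'   [evolve_trait_bm()]).
#' @param meta_meanlog,meta_sdlog log-normal abundance parameters across
#'   species-level clusters (default 0 and 0.5; strain-level spread adds to
#'   this, giving a realistic rank-abundance curve over ASVs).
#' @param strain_sdlog log-normal spread of the within-cluster strain
#'   profile (default 0.4, strains of one population have comparable pool
#'   abundances).
#' @param process assembly process for gut and rearing-water samples.
#' @param env optional named per-group environmental optima in absolute
#'   trait units (group ids `"<treatment>.<strain>"`). By default optima are
#'   placed by quantile of the realized tip traits, so they always fall in
#'   occupied niche space at a controlled selectivity (`target_band_mass`):
#'   one optimum shared by all groups for homogeneous selection, one per
#'   water treatment on opposite sides of the trait median for
#'   heterogeneous selection (separation at least `env_separation` times
#'   the selection width).
#' @param target_band_mass fraction of metacommunity mass the Gaussian
#'   filter should pass (default 0.2); optima are placed on the trait axis
#'   to hit this selectivity, on opposite sides of the trait median for the
#'   two treatments under heterogeneous selection.
#' @param env_separation minimum separation of the two optima in units of
#'   the selection width (default 3).
#' @param selection_width Gaussian filter width sigma as a fraction of the
#'   realized tip-trait standard deviation (default 0.25; ignored under
#'   `neutral`).
#' @param drift_theta Dirichlet drift concentration applied per gut sample
#'   within its flask (default 60).
#' @param flask_theta cluster-level Dirichlet founder concentration applied
#'   once per flask (default 30): which populations establish in a flask is
#'   a stochastic founder event, constrained by selection.
#' @param strain_theta within-cluster Dirichlet founder concentration
#'   (default 0.3): which one or two ASV strain variants of an established
#'   population dominate varies flask to flask, giving the low ASV-level
#'   sharing of real replicate communities.
#' @param strain_mix fraction of the metacommunity within-cluster strain
#'   profile retained in every flask's founder community (default 0: gut
#'   colonization is winner-dominated).
#' @param rw_theta drift concentration for rearing-water samples (default
#'   300): the water community is far less bottlenecked than a gut.
#' @param rw_strain_mix fraction of the full selection-weight profile
#'   (all strains of all selected populations) mixed into the rearing
#'   water (default 0.45), making RW samples strain-rich and dense, as
#'   sequenced water communities are.
#' @param dispersal_mix mass-effect fraction of the unfiltered metacommunity
#'   mixed into every sample (default 0.002), a trace immigrant tail as in
#'   real communities.
#' @param read_depth reads per sample (default 11000).
#' @param treatments,strains factor levels of the 2 x 2 design.
#' @param flasks_per_group replicate flasks per treatment-strain cell
#'   (default 4).
#' @param guts_per_flask individual gut samples per flask (default 4).
#' @param aw_days sampling days for the added-water communities (default
#'   14, 16, 18, 21 days post hatching).
#' @param aw_mix weight of the shared metacommunity in each added-water
#'   mixture (default 0.5); the remainder comes from a treatment-specific
#'   secondary metacommunity.
#' @param n_controls negative-control samples (default 2).
#' @param contamination_rate fraction of taxa leaking into each control
#'   (default 0.02); 0 disables contamination.
#' @param contamination_max_reads per-taxon read cap within one control
#'   (default 3, keeping most contaminants below the default QC exception
#'   cap).
#' @param master_seed seed from which all randomness derives.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 200, n_species = 50,
                            cluster_depth = 0.02,
                            birth_rate = 1, bm_rate = 1,
                            eb_rate = 1,
                            meta_meanlog = 0, meta_sdlog = 0.5,
                            strain_sdlog = 0.4,
                            process = c("homogeneous_selection",
                                        "heterogeneous_selection", "neutral"),
                            env = NULL, target_band_mass = 0.2,
                            env_separation = 3,
                            selection_width = 0.25, drift_theta = 60,
                            flask_theta = 30, strain_theta = 0.3,
                            strain_mix = 0,
                            dispersal_mix = 0.002,
                            rw_theta = 300, rw_strain_mix = 0.45,
                            read_depth = 11000,
                            treatments = c("Add-r", "Add-K"),
                            strains = c("wild", "aquaculture"),
                            flasks_per_group = 4, guts_per_flask = 4,
                            aw_days = c(14L, 16L, 18L, 21L), aw_mix = 0.5,
                            n_controls = 2, contamination_rate = 0.02,
                            contamination_max_reads = 3, master_seed = 1) {
  process <- match.arg(process)
  stopifnot(n_taxa >= 2, n_species >= 2, n_species <= n_taxa,
            cluster_depth >= 0, read_depth >= 1, flasks_per_group >= 1,
            guts_per_flask >= 1, n_controls >= 0,
            contamination_rate >= 0, contamination_rate <= 1,
            aw_mix >= 0, aw_mix <= 1, drift_theta > 0, flask_theta > 0,
            rw_theta > 0, rw_strain_mix >= 0, rw_strain_mix <= 1,
            strain_theta > 0, strain_mix >= 0, strain_mix <= 1,
            eb_rate >= 0,
            dispersal_mix >= 0, dispersal_mix <= 1)
  if (process != "neutral" && selection_width <= 0)
    stop("selection_width must be positive unless process is neutral")
  groups <- as.vector(outer(treatments, strains, paste, sep = "."))
  if (!is.null(env)) {
    missing <- setdiff(groups, names(env))
    if (length(missing))
      stop("env lacks groups: ", paste(missing, collapse = ", "))
    env <- env[groups]
  }
  stopifnot(target_band_mass > 0, target_band_mass < 1)
  structure(list(n_taxa = n_taxa, n_species = n_species,
                 cluster_depth = cluster_depth,
                 birth_rate = birth_rate, bm_rate = bm_rate,
                 eb_rate = eb_rate,
                 meta_meanlog = meta_meanlog, meta_sdlog = meta_sdlog,
                 strain_sdlog = strain_sdlog,
                 process = process, env = env,
                 target_band_mass = target_band_mass,
                 env_separation = env_separation,
                 selection_width = selection_width,
                 drift_theta = drift_theta, flask_theta = flask_theta,
                 strain_theta = strain_theta, strain_mix = strain_mix,
                 rw_theta = rw_theta, rw_strain_mix = rw_strain_mix,
                 dispersal_mix = dispersal_mix,
                 read_depth = read_depth,
                 treatments = treatments, strains = strains,
                 flasks_per_group = flasks_per_group,
                 guts_per_flask = guts_per_flask,
                 aw_days = as.integer(aw_days), aw_mix = aw_mix,
                 n_controls = n_controls,
                 contamination_rate = contamination_rate,
                 contamination_max_reads = contamination_max_reads,
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

## deterministic sub-seed derivation, kept within 32-bit integer range
sub_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1009 + k) %% 2147483647)
}

## fraction of metacommunity mass passed by a Gaussian filter at env
band_mass <- function(env, meta, traits, sigma) {
  sum(meta * exp(-(traits - env)^2 / (2 * sigma^2))) / sum(meta)
}

## per-group optima: explicit, or placed so the filter passes a target
## fraction of metacommunity mass (selectivity is then comparable across
## tree/trait realizations)
resolve_env <- function(cf, meta, traits, sigma) {
  groups <- as.vector(outer(cf$treatments, cf$strains, paste, sep = "."))
  if (!is.null(cf$env)) return(cf$env[groups])
  if (!is.finite(sigma))
    return(stats::setNames(rep(0, length(groups)), groups))
  grid <- seq(min(traits), max(traits), length.out = 512)
  mass <- vapply(grid, band_mass, 1, meta = meta, traits = traits,
                 sigma = sigma)
  if (cf$process == "heterogeneous_selection") {
    mid <- stats::median(traits)
    ok <- abs(mass - cf$target_band_mass) < 0.25 * cf$target_band_mass
    lo <- which(ok & grid <= mid)
    hi <- which(ok & grid > mid)
    # most extreme admissible optima: bands on opposite niche flanks
    e1 <- if (length(lo)) grid[min(lo)] else
      grid[which.min(abs(mass - cf$target_band_mass) + (grid > mid) * 1e6)]
    e2 <- if (length(hi)) grid[max(hi)] else
      grid[which.min(abs(mass - cf$target_band_mass) + (grid <= mid) * 1e6)]
    if (e2 - e1 < cf$env_separation * sigma) {
      ctr <- (e1 + e2) / 2
      e1 <- ctr - cf$env_separation * sigma / 2
      e2 <- ctr + cf$env_separation * sigma / 2
    }
    side <- ifelse(sub("\\..*", "", groups) == cf$treatments[1], e1, e2)
    stats::setNames(side, groups)
  } else {
    env1 <- grid[which.min(abs(mass - cf$target_band_mass))]
    stats::setNames(rep(env1, length(groups)), groups)
  }
}

#' Generate a full synthetic experiment with known assembly processes
#'
#' Builds a Yule tree, Brownian niche traits, a log-normal metacommunity,
#' and assembles every sample of the emulated design: gut samples (several
#' individuals per flask), one rearing-water sample per flask (both under
#' the configured process and drift), repeated added-water samples (neutral
#' draws from treatment-specific metacommunity mixtures), and negative
#' controls carrying sparse contamination for QC tests. All randomness
#' derives from `config$master_seed`.
#'
#' @param config a [scenario_config()].
#' @return a list: `table` (a `count_table` including control samples),
#'   `metadata` (validated sample metadata), `tree`, `traits`, and `truth`,
#'   a manifest recording the generating process, optima, widths and seeds.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  backbone <- simulate_tree(cf$n_species, cf$birth_rate,
                            seed = sub_seed(cf$master_seed, 1))
  sizes <- rep(cf$n_taxa %/% cf$n_species, cf$n_species)
  extra <- cf$n_taxa - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tree <- expand_microdiversity(backbone, sizes, cf$cluster_depth,
                                seed = sub_seed(cf$master_seed, 90))
  cluster_id <- rep(seq_along(sizes), sizes)
  traits <- evolve_trait_bm(tree, cf$bm_rate, seed = sub_seed(cf$master_seed, 2),
                            eb_rate = cf$eb_rate)
  taxa <- tree$tip.label
  set.seed(sub_seed(cf$master_seed, 3))
  cl_ab <- stats::rlnorm(cf$n_species, cf$meta_meanlog, cf$meta_sdlog)
  meta <- cl_ab[cluster_id] * stats::rlnorm(cf$n_taxa, 0, cf$strain_sdlog)
  meta <- stats::setNames(meta / sum(meta), taxa)
  aw_meta <- lapply(seq_along(cf$treatments), function(i) {
    set.seed(sub_seed(cf$master_seed, 3 + i))
    m2 <- stats::rlnorm(cf$n_taxa, cf$meta_meanlog, cf$meta_sdlog)
    m2 <- m2 / sum(m2)
    mixed <- cf$aw_mix * meta + (1 - cf$aw_mix) * m2
    stats::setNames(mixed / sum(mixed), taxa)
  })
  names(aw_meta) <- cf$treatments
  sigma <- if (cf$process == "neutral") Inf else
    cf$selection_width * stats::sd(traits)
  env <- resolve_env(cf, meta, traits, sigma)
  counts <- list()
  md <- list()
  k <- 0L
  add <- function(id, reads, type, treatment, strain, flask, day) {
    k <<- k + 1L
    counts[[k]] <<- reads
    md[[k]] <<- data.frame(sample_id = id, sample_type = type,
                           water_treatment = treatment, strain = strain,
                           flask_id = flask, day_dph = day,
                           stringsAsFactors = FALSE)
    names(counts)[k] <<- id
  }
  s <- 100L
  for (tr in cf$treatments) {
    for (st in cf$strains) {
      grp <- paste(tr, st, sep = ".")
      env_g <- env[[grp]]
      for (fl in seq_len(cf$flasks_per_group)) {
        flask <- sprintf("F_%s_%s_%d", tr, st, fl)
        s <- s + 1L
        set.seed(sub_seed(cf$master_seed, s))
        p_flask <- founder_weights(
          selection_weights(meta, traits, env_g, sigma),
          cluster_id, cf$flask_theta, cf$strain_theta, cf$strain_mix)
        names(p_flask) <- taxa
        for (ind in seq_len(cf$guts_per_flask)) {
          s <- s + 1L
          add(sprintf("G_%s_%s_%d_%d", tr, st, fl, ind),
              assemble_sample(p_flask, traits, 0, Inf, cf$read_depth,
                              seed = sub_seed(cf$master_seed, s),
                              theta = cf$drift_theta,
                              dispersal = cf$dispersal_mix,
                              dispersal_source = meta),
              "gut", tr, st, flask, 22L)
        }
        s <- s + 1L
        p_rw <- (1 - cf$rw_strain_mix) * p_flask +
          cf$rw_strain_mix * selection_weights(meta, traits, env_g, sigma)
        add(sprintf("RW_%s_%s_%d", tr, st, fl),
            assemble_sample(p_rw, traits, 0, Inf, cf$read_depth,
                            seed = sub_seed(cf$master_seed, s),
                            theta = cf$rw_theta,
                            dispersal = cf$dispersal_mix,
                            dispersal_source = meta),
            "rearing_water", tr, st, flask, 22L)
      }
    }
    for (day in cf$aw_days) {
      s <- s + 1L
      add(sprintf("AW_%s_%d", tr, day),
          assemble_sample(aw_meta[[tr]], traits, 0, Inf, cf$read_depth,
                          seed = sub_seed(cf$master_seed, s)),
          "added_water", tr, "none", NA_character_, day)
    }
  }
  n_contam <- round(cf$contamination_rate * cf$n_taxa)
  for (nc in seq_len(cf$n_controls)) {
    s <- s + 1L
    set.seed(sub_seed(cf$master_seed, s))
    reads <- stats::setNames(integer(cf$n_taxa), taxa)
    if (n_contam > 0) {
      picked <- sample(taxa, n_contam)
      reads[picked] <- sample.int(cf$contamination_max_reads, n_contam,
                                  replace = TRUE)
    }
    add(sprintf("NC_%d", nc), reads, "negative_control", "none", "none",
        NA_character_, NA_integer_)
  }
  m <- do.call(cbind, counts)
  rownames(m) <- taxa
  metadata <- validate_metadata(do.call(rbind, md))
  truth <- list(process = cf$process, env = env, sigma = sigma,
                drift_theta = cf$drift_theta, flask_theta = cf$flask_theta,
                strain_theta = cf$strain_theta, strain_mix = cf$strain_mix,
                dispersal_mix = cf$dispersal_mix,
                read_depth = cf$read_depth,
                master_seed = cf$master_seed,
                n_gut = sum(metadata$sample_type == "gut"),
                n_rearing_water = sum(metadata$sample_type == "rearing_water"),
                n_added_water = sum(metadata$sample_type == "added_water"),
                n_controls = cf$n_controls)
  list(table = count_table(m), metadata = metadata, tree = tree,
       traits = traits, truth = truth)
}

#' Write a truth manifest as flat key = value text
#'
#' @param truth the `truth` element of [generate_experiment()] output.
#' @param path file path.
#' @export
write_truth_manifest <- function(truth, path) {
  flat <- unlist(truth)
  writeLines(paste(names(flat), unname(flat), sep = " = "), path)
  invisible(path)
}
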