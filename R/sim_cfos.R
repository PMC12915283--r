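#' Configuration for a simulated c-Fos mapping study
#'
#' Describes a three-group (CTR / DEM / OBS) whole-brain c-Fos study with
#' observer-demonstrator dyads. Regional densities are lognormal; activation
#' is a log-scale shift planted in the configured region sets; within-dyad
#' coupling is induced by one Gaussian latent factor per dyad, shared by
#' both animals and by all coupled regions on the log scale (a dyad-level
#' shared state, which also co-activates the coupled regions within each
#' group), with a loading chosen so the implied Pearson correlation of the
#' *densities* equals `dyad_coupling_r`.
#'
#' The default group sizes (6 CTR, 7 DEM, 7 OBS) and the 88-region activated
#' set of which half is shared between OBS and DEM mirror the structure of
#' the dyadic paradigm this generator emulates.
#'
#' @param n_regions number of brain regions in the table.
#' @param n_per_group named counts `c(CTR, DEM, OBS)`; DEM and OBS counts
#'   must be equal (animals are paired into dyads).
#' @param activated_regions_dem indices of regions upregulated in DEM.
#' @param activated_regions_obs indices upregulated in OBS (in the emulated
#'   design a superset of the DEM set).
#' @param effect_log_fold log-scale group shift in activated regions.
#' @param dyad_coupling_r target within-dyad Pearson correlation of densities
#'   in `coupled_regions` (0 <= r < 1).
#' @param coupled_regions indices carrying the shared dyad factor; must be a
#'   subset of both activated sets.
#' @param baseline_log_mean,baseline_log_sd lognormal density parameters
#'   (density in cells/mm^3).
#' @param seed integer seed.
#' @return object of class `cfos_sim_config`.
#' @export
cfos_sim_config <- function(n_regions = 120,
                            n_per_group = c(CTR = 6, DEM = 7, OBS = 7),
                            activated_regions_dem = 1:44,
                            activated_regions_obs = 1:88,
                            effect_log_fold = 1,
                            dyad_coupling_r = 0.9,
                            coupled_regions = 1:8,
                            baseline_log_mean = log(50),
                            baseline_log_sd = 0.5,
                            seed = 1L) {
  n_regions <- .check_count(n_regions, "n_regions")
  if (!all(c("CTR", "DEM", "OBS") %in% names(n_per_group))) {
    stop("`n_per_group` must be named c(CTR, DEM, OBS)", call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("all group counts must be >= 1", call. = FALSE)
  if (n_per_group[["DEM"]] != n_per_group[["OBS"]]) {
    stop("DEM and OBS counts must match (dyads)", call. = FALSE)
  }
  if (dyad_coupling_r < 0 || dyad_coupling_r >= 1) {
    stop("`dyad_coupling_r` must be in [0, 1)", call. = FALSE)
  }
  rng <- function(x) length(x) == 0 || (min(x) >= 1 && max(x) <= n_regions)
  if (!rng(activated_regions_dem) || !rng(activated_regions_obs) ||
      !rng(coupled_regions)) {
    stop("region index sets must lie within 1..n_regions", call. = FALSE)
  }
  shared <- intersect(activated_regions_dem, activated_regions_obs)
  if (length(coupled_regions) > 0 && !all(coupled_regions %in% shared)) {
    stop("`coupled_regions` must be activated in both DEM and OBS", call. = FALSE)
  }
  if (baseline_log_sd <= 0) stop("`baseline_log_sd` must be > 0", call. = FALSE)
  structure(
    list(
      n_regions = n_regions,
      n_per_group = c(CTR = as.integer(n_per_group[["CTR"]]),
                      DEM = as.integer(n_per_group[["DEM"]]),
                      OBS = as.integer(n_per_group[["OBS"]])),
      activated_regions_dem = as.integer(activated_regions_dem),
      activated_regions_obs = as.integer(activated_regions_obs),
      effect_log_fold = effect_log_fold,
      dyad_coupling_r = dyad_coupling_r,
      coupled_regions = as.integer(coupled_regions),
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      seed = as.integer(seed)
    ),
    class = "cfos_sim_config"
  )
}

# Log-scale latent loading implied by a target Pearson correlation of
# lognormal densities: corr_nat = (exp(rho*s^2)-1)/(exp(s^2)-1), inverted.
.log_rho_for_natural_r <- function(r, s) {
  if (r == 0) return(0)
  log1p(r * expm1(s^2)) / s^2
}

#' Simulate a per-animal per-region c-Fos table
#'
#' Draws lognormal densities, plants group activation shifts and a
#' within-dyad shared latent factor, fixes region volumes (constant across
#' animals, as atlas volumes are), and derives integer cell counts so that
#' `density == count / volume` holds exactly.
#'
#' @param config a [cfos_sim_config()].
#' @return a region table (see [compute_density()]) with columns `animal_id`,
#'   `group`, `dyad_id`, `region_acronym`, `count`, `volume_mm3`, `density`.
#'   Ground truth is attached as attribute `"truth"`: list with
#'   `activated_dem`, `activated_obs`, `coupled` (region acronyms) and
#'   `pairing` (the true OBS-DEM dyad map, see [dyad_pairing()]).
#' @export
simulate_cfos_study <- function(config) {
  if (!inherits(config, "cfos_sim_config")) {
    stop("`config` must be a cfos_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  nr <- config$n_regions
  ng <- config$n_per_group
  regions <- sprintf("R%03d", seq_len(nr))
  volumes <- rlnorm(nr, meanlog = log(1.5), sdlog = 0.6)
  s <- config$baseline_log_sd
  rho <- .log_rho_for_natural_r(config$dyad_coupling_r, s)

  groups <- rep(c("CTR", "DEM", "OBS"), times = ng)
  n_animals <- sum(ng)
  animal_id <- sprintf("%s%02d", tolower(groups),
                       unlist(lapply(ng, seq_len), use.names = FALSE))
  n_dyads <- ng[["DEM"]]
  dyad_of <- rep(NA_integer_, n_animals)
  dyad_of[groups == "DEM"] <- seq_len(n_dyads)
  dyad_of[groups == "OBS"] <- seq_len(n_dyads)

  # log-density: baseline + group shift + shared dyad factor + residual
  shift <- matrix(0, nrow = nr, ncol = n_animals)
  shift[config$activated_regions_dem, groups == "DEM"] <- config$effect_log_fold
  shift[config$activated_regions_obs, groups == "OBS"] <- config$effect_log_fold
  eps <- matrix(rnorm(nr * n_animals), nr, n_animals)
  if (rho > 0 && length(config$coupled_regions) > 0) {
    # one latent factor per dyad, shared by both animals and by all coupled
    # regions: a dyad-level shared state that couples the pair and
    # co-activates the shared network
    lat <- rnorm(n_dyads)
    nc <- length(config$coupled_regions)
    for (g in c("DEM", "OBS")) {
      cols <- which(groups == g)
      eps[config$coupled_regions, cols] <-
        sqrt(rho) * matrix(lat[dyad_of[cols]], nc, length(cols), byrow = TRUE) +
        sqrt(1 - rho) * eps[config$coupled_regions, cols]
    }
  }
  logd <- config$baseline_log_mean + shift + s * eps
  counts <- round(exp(logd) * volumes)

  tab <- data.frame(
    animal_id = rep(animal_id, each = nr),
    group = rep(groups, each = nr),
    dyad_id = rep(dyad_of, each = nr),
    region_acronym = rep(regions, times = n_animals),
    count = as.vector(counts),
    volume_mm3 = rep(volumes, times = n_animals)
  )
  tab <- compute_density(tab)
  attr(tab, "truth") <- list(
    activated_dem = regions[config$activated_regions_dem],
    activated_obs = regions[config$activated_regions_obs],
    coupled = regions[config$coupled_regions],
    pairing = dyad_pairing(
      obs = animal_id[groups == "OBS"][order(dyad_of[groups == "OBS"])],
      dem = animal_id[groups == "DEM"][order(dyad_of[groups == "DEM"])]
    )
  )
  tab
}

#' Read / write region tables
#'
#' Plain CSV with columns `animal_id`, `group`, `dyad_id`, `region_acronym`,
#' `count`, `volume_mm3` (and `density` if present).
#'
#' @param table region table data.frame.
#' @param path file path.
#' @export
write_region_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
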