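#' Add c-Fos density to a region table
#'
#' Density is the raw labeled-cell count normalized by the atlas volume of
#' the region: `density = count / volume_mm3` (cells/mm^3).
#'
#' @param table data.frame with at least `region_acronym`, `count`,
#'   `volume_mm3` columns (counts >= 0, volumes > 0).
#' @return the table with a `density` column added (recomputed if present).
#' @export
compute_density <- function(table) {
  req <- c("region_acronym", "count", "volume_mm3")
  if (!all(req %in% names(table))) {
    stop("region table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(table$volume_mm3) | table$volume_mm3 <= 0
  if (any(bad)) {
    stop("zero or missing volume for region(s): ",
         paste(unique(table$region_acronym[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(table$count < 0)) stop("counts must be >= 0", call. = FALSE)
  table$density <- table$count / table$volume_mm3
  table
}

#' Screen regions for differential activation
#'
#' Runs one two-sided Mann-Whitney U test per region comparing c-Fos
#' densities between two groups, flagging regions with `p < alpha`
#' (default 0.05). Deliberately applies **no** multiple-comparison
#' correction: at the small group sizes of these studies the screen is
#' exploratory and over-correction would inflate type II errors. The
#' direction of change is the sign of the median difference (`group_a`
#' minus `group_b`).
#'
#' @param table region table with `density` (see [compute_density()]).
#' @param group_a,group_b group labels to compare (e.g. `"OBS"`, `"CTR"`);
#'   `group_a` is the condition of interest.
#' @param alpha significance level.
#' @param exclude_regions optional character vector of region acronyms to
#'   drop before screening (e.g. hindbrain areas).
#' @return object of class `activation_screen`: data.frame with one row per
#'   region (`region`, `median_a`, `median_b`, `U`, `p`, `significant`,
#'   `direction`), with `alpha` and the group labels as attributes.
#' @export
differential_activation <- function(table, group_a, group_b, alpha = 0.05,
                                    exclude_regions = NULL) {
  if (!"density" %in% names(table)) table <- compute_density(table)
  if (!is.null(exclude_regions)) {
    table <- table[!(table$region_acronym %in% exclude_regions), ]
  }
  ta <- table[table$group == group_a, ]
  tb <- table[table$group == group_b, ]
  regions <- sort(unique(table$region_acronym))
  rows <- lapply(regions, function(rg) {
    da <- ta$density[ta$region_acronym == rg]
    db <- tb$density[tb$region_acronym == rg]
    if (length(da) < 3 || length(db) < 3) {
      stop(sprintf("region %s has < 3 animals in a group", rg), call. = FALSE)
    }
    mw <- mann_whitney(da, db)
    md <- median(da) - median(db)
    data.frame(
      region = rg, median_a = median(da), median_b = median(db),
      U = mw$U, p = mw$p, significant = mw$p < alpha,
      direction = if (md > 0) "up" else if (md < 0) "down" else "none"
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("activation_screen", "data.frame"),
            alpha = alpha, group_a = group_a, group_b = group_b)
}

#' Interregional co-activation matrix
#'
#' Because each animal contributes a single activation index per region,
#' co-activation is estimated *across subjects*: the Pearson correlation of
#' regional densities over the animals of one group, for every region pair.
#' The diagonal is 1 by definition; pairs involving a zero-variance region
#' are recorded as `NA` (undefined), never silently zero.
#'
#' @param table region table with `density`.
#' @param group group label.
#' @return symmetric correlation matrix (regions x regions) of class
#'   `coactivation_matrix`.
#' @export
coactivation_matrix <- function(table, group) {
  if (!"density" %in% names(table)) table <- compute_density(table)
  tg <- table[table$group == group, ]
  regions <- sort(unique(tg$region_acronym))
  animals <- unique(tg$animal_id)
  if (length(animals) < 3) stop("group needs >= 3 animals", call. = FALSE)
  if (length(regions) < 2) stop("need >= 2 regions", call. = FALSE)
  M <- matrix(NA_real_, length(animals), length(regions),
              dimnames = list(animals, regions))
  M[cbind(match(tg$animal_id, animals), match(tg$region_acronym, regions))] <-
    tg$density
  if (anyNA(M)) stop("every animal must have every region", call. = FALSE)
  zero_var <- apply(M, 2, sd) == 0
  C <- suppressWarnings(cor(M))
  C[zero_var, ] <- NA_real_
  C[, zero_var] <- NA_real_
  diag(C) <- 1
  structure(C, class = c("coactivation_matrix", "matrix", "array"))
}

#' Compare co-activation distributions between groups
#'
#' Collects the upper-triangle correlations of each group's co-activation
#' matrix (excluding the diagonal; undefined entries dropped and counted)
#' and compares the distributions with a Kruskal-Wallis test.
#'
#' @param matrices named list of [coactivation_matrix()] objects over the
#'   same region set.
#' @return list with `medians` (per group), `statistic`, `p`, `n_values`,
#'   `n_missing`.
#' @export
compare_coactivation <- function(matrices) {
  if (length(matrices) < 2) stop("need >= 2 matrices", call. = FALSE)
  dims <- lapply(matrices, function(m) colnames(m))
  if (!all(vapply(dims[-1], identical, logical(1), dims[[1]]))) {
    stop("matrices must share the same region set", call. = FALSE)
  }
  vals <- lapply(matrices, function(m) m[upper.tri(m)])
  n_missing <- vapply(vals, function(v) sum(is.na(v)), integer(1))
  vals <- lapply(vals, function(v) v[!is.na(v)])
  stacked <- data.frame(
    value = unlist(vals, use.names = FALSE),
    group = factor(rep(names(matrices), lengths(vals)))
  )
  kw <- kruskal.test(value ~ group, data = stacked)
  list(
    medians = vapply(vals, median, numeric(1)),
    statistic = unname(kw$statistic), p = kw$p.value,
    n_values = lengths(vals), n_missing = n_missing
  )
}
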