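# Mass-balance simulation of milk adulteration: design enumeration for the
# 24-adulterant / 5-category experiment and prediction of the apparent
# composition of adulterated samples as an FTIR milk analyser would read them.

# cryoscopic constant of water, degC * kg / mol
.KF_WATER <- 1.86
# Kjeldahl nitrogen-to-milk-protein conversion factor
.N_TO_PROTEIN <- 6.38
# linear solids-density coefficient, g/L per 1 % w/w added solids
.DENSITY_PER_SOLIDS <- 3.7

.adulterant_categories <- c("protein_rich", "nitrogen", "carbohydrate",
                            "preservative", "water")

#' Load the adulterant registry
#'
#' The 24 adulterants of the screening experiment with the composition
#' constants the mass-balance model needs: category, non-protein nitrogen
#' mass fraction, true protein fraction, solids fraction, molar mass and the
#' number of particles each formula unit contributes in solution (for the
#' freezing-point model; 0 for polymers and insoluble powders, whose
#' cryoscopic contribution is negligible).
#'
#' @param path optional CSV path; defaults to the bundled registry.
#' @return data.frame, one row per adulterant code.
#' @export
load_adulterant_registry <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("adulterant_registry.csv")
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "category", "nitrogen_fraction", "protein_fraction",
            "solids_fraction", "molar_mass", "dissociation_count")
  if (!all(need %in% names(reg))) stop("registry missing columns", call. = FALSE)
  if (!all(reg$category %in% .adulterant_categories)) {
    stop("unknown adulterant category: ",
         paste(setdiff(reg$category, .adulterant_categories), collapse = ", "),
         call. = FALSE)
  }
  frac <- reg[, c("nitrogen_fraction", "protein_fraction", "solids_fraction")]
  if (any(frac < 0 | frac > 1)) stop("registry fractions outside [0,1]", call. = FALSE)
  reg
}

#' Default per-level doses for single adulterations
#'
#' Grams of adulterant added per 100 g milk at levels 1..4, by category.
#' Water is dosed at 10/20/30/40 g, soluble/powder solids (protein-rich,
#' nitrogen, carbohydrate) at 0.5/1/2/4 g, preservatives and concealers at
#' 0.05/0.1/0.2/0.4 g. All values are configuration, not measurement.
#'
#' @return named list of length-4 numeric vectors, one per category.
#' @export
default_dose_levels <- function() {
  list(
    protein_rich = c(0.5, 1, 2, 4),
    nitrogen = c(0.5, 1, 2, 4),
    carbohydrate = c(0.5, 1, 2, 4),
    preservative = c(0.05, 0.1, 0.2, 0.4),
    water = c(10, 20, 30, 40)
  )
}

#' Enumerate the adulteration design
#'
#' Builds the full experimental design: every adulterant at 4 single levels
#' for each of the 3 milk pools (24 x 4 x 3 = 288 single recipes), plus the
#' combined recipes in which 100 g pool milk is first diluted with 40 g water
#' and an adulterant from the protein-rich, nitrogen or carbohydrate category
#' is then dosed to raise the apparent protein (or, for carbohydrates, the
#' apparent total solids) by 40\% of the milk's own content
#' ((5 + 5 + 7) x 3 = 51 combined recipes). Ordering is deterministic:
#' pool, then category, then code, then level.
#'
#' @param pools pool profile data.frame (uses column `pool_id`).
#' @param registry adulterant registry from [load_adulterant_registry]; may be
#'   a subset.
#' @param dose_levels per-category dose table, see [default_dose_levels].
#' @return data.frame of recipes: `pool_id`, `code`, `category`, `mode`
#'   (`"single"`/`"combined"`), `level` (NA for combined), `added_mass`
#'   (g per 100 g milk; NA for combined until solved), `water_added` (g),
#'   `target`.
#' @export
enumerate_design <- function(pools, registry, dose_levels = default_dose_levels()) {
  if (nrow(registry) == 0L) {
    return(data.frame(pool_id = character(0), code = character(0),
                      category = character(0), mode = character(0),
                      level = integer(0), added_mass = numeric(0),
                      water_added = numeric(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!all(registry$category %in% names(dose_levels))) {
    stop("dose_levels missing category: ",
         paste(setdiff(registry$category, names(dose_levels)), collapse = ", "),
         call. = FALSE)
  }
  cat_order <- match(registry$category, .adulterant_categories)
  reg <- registry[order(cat_order, registry$code), ]
  n_levels <- length(dose_levels[[1]])

  single <- do.call(rbind, lapply(pools$pool_id, function(p) {
    do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
      doses <- dose_levels[[reg$category[i]]]
      data.frame(pool_id = p, code = reg$code[i], category = reg$category[i],
                 mode = "single", level = seq_along(doses),
                 added_mass = doses, water_added = 0,
                 target = "none", stringsAsFactors = FALSE)
    }))
  }))

  comb_reg <- reg[reg$category %in% c("protein_rich", "nitrogen", "carbohydrate"), ]
  combined <- if (nrow(comb_reg)) {
    do.call(rbind, lapply(pools$pool_id, function(p) {
      data.frame(pool_id = p, code = comb_reg$code, category = comb_reg$category,
                 mode = "combined", level = NA_integer_,
                 added_mass = NA_real_, water_added = 40,
                 target = ifelse(comb_reg$category == "carbohydrate",
                                 "apparent_TS_+40%", "apparent_protein_+40%"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    single[0, ]
  }
  out <- rbind(single, combined)
  rownames(out) <- NULL
  out
}

# component masses (g) in `milk_mass` g of a milk described by `base`
.milk_masses <- function(base, milk_mass = 100) {
  list(
    protein = base$protein * milk_mass / 100,
    fat = base$fat * milk_mass / 100,
    ts = base$ts * milk_mass / 100,
    snf = base$snf * milk_mass / 100,
    lactose = base$lactose * milk_mass / 100,
    water = (100 - base$ts) * milk_mass / 100
  )
}

#' Solve the adulterant dose for a combined recipe
#'
#' For the combined adulterations the dose is defined by a ratio target:
#' the adulterant's apparent-protein contribution (true protein plus
#' 6.38 x non-protein nitrogen) must equal 40\% of the diluted milk's protein
#' mass, or, for carbohydrates, its solids contribution must equal 40\% of
#' the milk's total-solids mass. Closed form: dose = target_fraction x
#' milk component mass / adulterant channel fraction.
#'
#' @param base pool composition record (one row).
#' @param spec one registry row for the adulterant.
#' @param target `"apparent_protein_+40%"` or `"apparent_TS_+40%"`;
#'   `target_fraction` may override the 0.40.
#' @param milk_mass grams of milk in the recipe (before the 40 g water).
#' @param target_fraction the relative increase (0.40 for the +40\% targets).
#' @return dose in grams.
#' @export
combined_dose <- function(base, spec, target, milk_mass = 100,
                          target_fraction = 0.40) {
  target <- match.arg(target, c("apparent_protein_+40%", "apparent_TS_+40%"))
  mm <- .milk_masses(base, milk_mass)
  channel <- if (target == "apparent_protein_+40%") {
    spec$protein_fraction + .N_TO_PROTEIN * spec$nitrogen_fraction
  } else {
    spec$solids_fraction
  }
  if (channel <= 0) {
    stop("adulterant '", spec$code, "' contributes nothing to the ",
         target, " channel", call. = FALSE)
  }
  comp <- if (target == "apparent_protein_+40%") mm$protein else mm$ts
  target_fraction * comp / channel
}

#' Predict the apparent composition of an adulterated sample
#'
#' Two-component mass balance between `milk_mass` g of milk (plus optional
#' dilution water) and `added_mass` g of adulterant, read out as an FTIR milk
#' analyser would: every \% w/w channel is component mass over total mass.
#' Apparent protein gains the adulterant's true protein plus
#' 6.38 x its non-protein nitrogen (the Kjeldahl-equivalent effect of
#' nitrogen-rich compounds); the carbohydrate (lactose) channel gains the
#' solids of carbohydrate-category adulterants; total solids and
#' solids-non-fat gain every adulterant's solids. Density scales its excess
#' over 1000 g/L with the milk-solids concentration factor and rises by
#' 3.7 g/L per 1 \% w/w added solids. FPD scales with the milk water fraction
#' (dilution moves it toward zero) and gains 1.86 degC x molality x
#' dissociation count for dissolved low-molar-mass adulterants.
#'
#' @param base pool composition record (one row).
#' @param recipe one row from [enumerate_design]; combined recipes with
#'   `added_mass = NA` have their dose solved by [combined_dose].
#' @param spec matching registry row (defaults to a lookup in the bundled
#'   registry by `recipe$code`).
#' @param milk_mass grams of milk (default 100).
#' @return one-row composition data.frame with recipe metadata columns.
#' @export
apply_recipe <- function(base, recipe, spec = NULL, milk_mass = 100) {
  if (is.null(spec)) {
    reg <- load_adulterant_registry()
    spec <- reg[reg$code == recipe$code, ]
    if (nrow(spec) != 1L) stop("unknown adulterant code '", recipe$code, "'",
                               call. = FALSE)
  }
  added <- recipe$added_mass
  water_added <- recipe$water_added
  if (is.na(added)) {
    if (recipe$mode != "combined") stop("added_mass missing", call. = FALSE)
    added <- combined_dose(base, spec, recipe$target, milk_mass)
  }
  if (added < 0 || water_added < 0) stop("negative mass", call. = FALSE)

  mm <- .milk_masses(base, milk_mass)
  total <- milk_mass + water_added + added

  protein_add <- added * (spec$protein_fraction +
                            .N_TO_PROTEIN * spec$nitrogen_fraction)
  solids_add <- added * spec$solids_fraction
  carb_add <- if (spec$category == "carbohydrate") solids_add else 0

  protein <- (mm$protein + protein_add) / total * 100
  fat <- mm$fat / total * 100
  ts <- (mm$ts + solids_add) / total * 100
  snf <- (mm$snf + solids_add) / total * 100
  lactose <- (mm$lactose + carb_add) / total * 100

  # density: milk-solids excess diluted by concentration, plus added solids
  milk_conc <- milk_mass / total
  added_solids_pct <- solids_add / total * 100
  density <- 1000 + (base$density - 1000) * milk_conc +
    .DENSITY_PER_SOLIDS * added_solids_pct

  # freezing point: solute concentration in the aqueous phase
  water_total <- mm$water + water_added + added * (1 - spec$solids_fraction)
  fpd <- base$fpd * mm$water / water_total
  if (spec$molar_mass > 0 && spec$dissociation_count > 0) {
    molality <- (added / spec$molar_mass * spec$dissociation_count) /
      (water_total / 1000)
    fpd <- fpd + .KF_WATER * molality
  }

  out <- data.frame(
    sample_id = sprintf("%s_%s_%s%s", recipe$pool_id, recipe$code, recipe$mode,
                        ifelse(is.na(recipe$level), "", paste0("_L", recipe$level))),
    pool_id = recipe$pool_id, code = recipe$code, category = spec$category,
    mode = recipe$mode, level = recipe$level, added_mass = added,
    water_added = water_added, target = recipe$target,
    protein = protein, fat = fat, ts = ts, snf = snf, lactose = lactose,
    density = density, fpd = fpd, origin = "adulterated",
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate the full adulterant test set
#'
#' Applies every recipe of [enumerate_design] to its pool profile, producing
#' the 339-sample adulterant test set (288 single + 51 combined) under the
#' default registry and dose table.
#'
#' @param pools pool profiles.
#' @param registry adulterant registry.
#' @param dose_levels per-category dose table.
#' @return composition data.frame with recipe metadata, one row per recipe.
#' @export
simulate_adulterant_set <- function(pools = load_table1_fixture()$pools,
                                    registry = load_adulterant_registry(),
                                    dose_levels = default_dose_levels()) {
  design <- enumerate_design(pools, registry, dose_levels)
  if (nrow(design) == 0L) return(design)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    recipe <- design[i, ]
    base <- pools[pools$pool_id == recipe$pool_id, ]
    spec <- registry[registry$code == recipe$code, ]
    apply_recipe(base, recipe, spec)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
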