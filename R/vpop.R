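## Virtual population generation: stratified covariate sampling with BMI and
## fat-free (lean body) mass derived per subject.

#' Stratum definitions for BMI and age
#'
#' Half-open intervals (lower bound inclusive, upper exclusive) used to
#' stratify the simulated populations: four adult BMI categories
#' (underweight < 18.5, healthy 18.5-<25, overweight 25-<30,
#' obese 30-<60 kg/m^2) and four age categories (2-<6, 6-<12, 12-<18 and
#' >= 18 years).
#'
#' @return A data.frame with columns `label`, `lower`, `upper`.
#' @export
#' @examples
#' bmi_groups()
#' age_groups()
bmi_groups <- function() {
  data.frame(
    label = c("underweight", "healthy", "overweight", "obese"),
    lower = c(10, 18.5, 25, 30),
    upper = c(18.5, 25, 30, 60),
    stringsAsFactors = FALSE
  )
}

#' @rdname bmi_groups
#' @export
age_groups <- function() {
  data.frame(
    label = c("2-<6 y", "6-<12 y", "12-<18 y", ">=18 y"),
    lower = c(2, 6, 12, 18),
    upper = c(6, 12, 18, Inf),
    stringsAsFactors = FALSE
  )
}

#' Body mass index
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2 (`weight / height^2`). Vectorized.
#' @export
#' @examples
#' compute_bmi(45, 1.50) # 20
compute_bmi <- function(weight_kg, height_m) {
  assert_number(weight_kg, "weight_kg", positive = TRUE)
  assert_number(height_m, "height_m", positive = TRUE)
  weight_kg / height_m^2
}

#' Fat-free (lean body) mass
#'
#' Janmahasatian fat-free mass, the standard pharmacometric body-size
#' covariate that corrects total weight for mass poorly accessible to IgG:
#' `9270 * WT / (6680 + 216 * BMI)` for males and
#' `9270 * WT / (8780 + 244 * BMI)` for females. Applied at all ages >= 2
#' years (a deliberate simplification; see the methods vignette). Note the
#' male form only yields FFM < weight for BMI > 11.99 kg/m^2; the population
#' generator therefore truncates BMI sampling at 12 kg/m^2.
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param bmi BMI in kg/m^2, in (10, 60).
#' @param sex `"male"` or `"female"`. Vectorized (recycled).
#' @return Fat-free mass in kilograms.
#' @export
#' @examples
#' compute_lbm(70, 22.5, "male")    # 56.23
#' compute_lbm(60, 22.9, "female")  # 38.71
compute_lbm <- function(weight_kg, bmi, sex) {
  assert_number(weight_kg, "weight_kg", positive = TRUE)
  assert_number(bmi, "bmi")
  if (any(bmi <= 10 | bmi >= 60)) stopf("`bmi` must lie in (10, 60)")
  if (!all(sex %in% c("male", "female"))) {
    stopf("`sex` must be \"male\" or \"female\"")
  }
  ifelse(sex == "male",
    9270 * weight_kg / (6680 + 216 * bmi),
    9270 * weight_kg / (8780 + 244 * bmi)
  )
}

assign_interval <- function(x, groups, what) {
  lo <- min(groups$lower)
  hi <- max(groups$upper)
  if (any(x < lo | x >= hi)) {
    stopf("%s out of range [%g, %g)", what, lo, hi)
  }
  idx <- findInterval(x, groups$lower) # lower-inclusive, upper-exclusive
  groups$label[idx]
}

#' Assign BMI and age stratum labels
#'
#' Lower-inclusive, upper-exclusive interval assignment against
#' [bmi_groups()] / [age_groups()].
#'
#' @param bmi BMI in kg/m^2, must lie in \[10, 60).
#' @param age Age in years, must be >= 2.
#' @return Character vector of stratum labels.
#' @export
#' @examples
#' assign_bmi_group(c(18.5, 29.99, 30)) # healthy, overweight, obese
#' assign_age_group(c(5.99, 12, 18))
assign_bmi_group <- function(bmi) {
  assert_number(bmi, "bmi")
  assign_interval(bmi, bmi_groups(), "bmi")
}

#' @rdname assign_bmi_group
#' @export
assign_age_group <- function(age) {
  assert_number(age, "age")
  assign_interval(age, age_groups(), "age")
}

## ---------------------------------------------------------------------------
## Covariate distribution parameters. These emulate the joint age/sex/height/
## BMI structure of the US general population (NHANES-like marginals) without
## shipping any survey data; everything is overridable through the `population`
## section of a config file.

#' Default covariate distribution parameters
#'
#' Parametric distributions used by [sample_population()]: sex is Bernoulli(0.5);
#' adult age is Uniform(18, 80) years with sex-specific Normal heights; BMI is
#' lognormal (given as median and geometric SD) truncated to the stratum
#' interval. Pediatric heights follow a packaged age-sex median growth curve
#' with 4% CV, and pediatric BMI is lognormal around an age-dependent median
#' (15.8 kg/m^2 at age 4 rising to 20.5 at age 15), truncated to \[12, 40).
#'
#' @return A nested list of distribution parameters.
#' @export
default_covariate_params <- function() {
  list(
    sex_prob_male = 0.5,
    adult = list(
      age_range = c(18, 80),
      height_mean = c(male = 1.75, female = 1.62),
      height_sd = 0.07,
      # overall adult BMI (used for the >= 18 y stratum of the age-stratified
      # population)
      bmi_median = 27.0, bmi_gsd = 1.22, bmi_range = c(15, 60)
    ),
    # per-BMI-stratum lognormal parameters (adults); truncated to the stratum
    # interval intersected with [12, 60) to stay clear of the FFM formula's
    # degenerate region below BMI 12
    bmi_strata = list(
      underweight = list(median = 17.5, gsd = 1.05),
      healthy     = list(median = 21.5, gsd = 1.10),
      overweight  = list(median = 27.3, gsd = 1.05),
      obese       = list(median = 33.0, gsd = 1.12)
    ),
    pediatric = list(
      height_cv = 0.04,
      # median stature (m) by age and sex, interpolated linearly
      height_curve = list(
        age = c(2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18),
        male = c(0.87, 0.95, 1.02, 1.09, 1.15, 1.28, 1.38, 1.49, 1.63, 1.73, 1.76),
        female = c(0.86, 0.94, 1.01, 1.08, 1.15, 1.27, 1.38, 1.51, 1.60, 1.62, 1.63)
      ),
      # median BMI by age, interpolated linearly
      bmi_curve = list(
        age = c(2, 4, 8, 12, 15, 18),
        median = c(16.2, 15.8, 16.4, 18.2, 20.5, 21.5)
      ),
      bmi_gsd = 1.15,
      bmi_range = c(12, 40)
    )
  )
}

pediatric_height_median <- function(age, sex, params) {
  hc <- params$pediatric$height_curve
  m <- stats::approx(hc$age, hc$male, xout = pmin(age, max(hc$age)), rule = 2)$y
  f <- stats::approx(hc$age, hc$female, xout = pmin(age, max(hc$age)), rule = 2)$y
  ifelse(sex == "male", m, f)
}

pediatric_bmi_median <- function(age, params) {
  bc <- params$pediatric$bmi_curve
  stats::approx(bc$age, bc$median, xout = pmin(age, max(bc$age)), rule = 2)$y
}

#' Specify a stratified virtual population
#'
#' @param stratify_by `"bmi"` (four adult BMI strata) or `"age"` (three
#'   pediatric and one adult age stratum).
#' @param n_per_group Number of subjects per stratum (default 1000).
#' @param seed Integer seed; identical seed and spec reproduce the population
#'   byte-for-byte.
#' @param groups Optional data.frame of `(label, lower, upper)` half-open
#'   intervals; defaults to [bmi_groups()] / [age_groups()].
#' @param covariate_params Distribution parameters; see
#'   [default_covariate_params()].
#' @return An object of class `igsim_popspec`.
#' @export
population_spec <- function(stratify_by = c("bmi", "age"), n_per_group = 1000,
                            seed = 1L, groups = NULL,
                            covariate_params = default_covariate_params()) {
  stratify_by <- match.arg(stratify_by)
  groups <- groups %||% if (stratify_by == "bmi") bmi_groups() else age_groups()
  if (!all(c("label", "lower", "upper") %in% names(groups))) {
    stopf("`groups` needs columns label, lower, upper")
  }
  if (is.unsorted(groups$lower) || any(groups$upper[-nrow(groups)] != groups$lower[-1])) {
    stopf("`groups` must be ordered, non-overlapping half-open intervals")
  }
  if (n_per_group <= 0) stopf("`n_per_group` must be > 0")
  structure(
    list(stratify_by = stratify_by, groups = groups,
         n_per_group = as.integer(n_per_group), seed = as.integer(seed),
         covariate_params = covariate_params),
    class = "igsim_popspec"
  )
}

## Rejection-sample one stratum; cap of 1000 * n draws guards against
## misconfigured intervals.
sample_stratum <- function(spec, g) {
  p <- spec$covariate_params
  n <- spec$n_per_group
  label <- spec$groups$label[g]
  lower <- spec$groups$lower[g]
  upper <- spec$groups$upper[g]
  cap <- 1000 * n
  drawn <- 0L
  out <- vector("list", 0L)
  got <- 0L
  while (got < n) {
    m <- min(max(2L * (n - got), 100L), cap - drawn)
    if (m <= 0L) {
      stopf("failed to generate stratum \"%s\" within %d draws", label, cap)
    }
    drawn <- drawn + m
    sex <- ifelse(stats::runif(m) < p$sex_prob_male, "male", "female")
    if (spec$stratify_by == "bmi") {
      # adults only; BMI is the stratifying covariate
      age <- stats::runif(m, p$adult$age_range[1], p$adult$age_range[2])
      height <- stats::rnorm(m, p$adult$height_mean[sex], p$adult$height_sd)
      bp <- p$bmi_strata[[label]]
      bmi <- stats::rlnorm(m, log(bp$median), log(bp$gsd))
      keep <- bmi >= max(lower, 12) & bmi < upper & height > 0.5
    } else {
      age <- stats::runif(m, lower, min(upper, p$adult$age_range[2]))
      is_adult <- age >= 18
      height <- numeric(m)
      bmi <- numeric(m)
      if (any(is_adult)) {
        height[is_adult] <- stats::rnorm(sum(is_adult),
                                         p$adult$height_mean[sex[is_adult]],
                                         p$adult$height_sd)
        bmi[is_adult] <- stats::rlnorm(sum(is_adult), log(p$adult$bmi_median),
                                       log(p$adult$bmi_gsd))
      }
      if (any(!is_adult)) {
        hmed <- pediatric_height_median(age[!is_adult], sex[!is_adult], p)
        height[!is_adult] <- stats::rnorm(sum(!is_adult), hmed,
                                          p$pediatric$height_cv * hmed)
        bmed <- pediatric_bmi_median(age[!is_adult], p)
        bmi[!is_adult] <- stats::rlnorm(sum(!is_adult), log(bmed),
                                        log(p$pediatric$bmi_gsd))
      }
      rng <- ifelse(is_adult, p$adult$bmi_range[1], p$pediatric$bmi_range[1])
      rng_hi <- ifelse(is_adult, p$adult$bmi_range[2], p$pediatric$bmi_range[2])
      keep <- bmi >= rng & bmi < rng_hi & height > 0.5
    }
    if (any(keep)) {
      take <- which(keep)[seq_len(min(sum(keep), n - got))]
      out[[length(out) + 1L]] <- data.frame(
        age_years = age[take], sex = sex[take], height_m = height[take],
        bmi = bmi[take], stringsAsFactors = FALSE
      )
      got <- got + length(take)
    }
  }
  do.call(rbind, out)
}

#' Generate a stratified virtual population
#'
#' Draws exactly `n_per_group` subjects per stratum by rejection sampling from
#' the configured covariate distributions, then derives weight
#' (`BMI * height^2`), fat-free mass ([compute_lbm()]) and both stratum
#' labels per subject. BMI-stratified populations contain adults only.
#'
#' @param spec An [population_spec()] object.
#' @return A data.frame of class `igsim_subjects` with columns `subject_id`,
#'   `age_years`, `sex`, `height_m`, `weight_kg`, `bmi`, `lbm_kg`,
#'   `bmi_group`, `age_group`, plus attributes `stratify_by` and `seed`.
#' @export
#' @examples
#' pop <- sample_population(population_spec("bmi", n_per_group = 5, seed = 42))
#' table(pop$bmi_group)
sample_population <- function(spec) {
  if (!inherits(spec, "igsim_popspec")) stopf("`spec` must be a population_spec()")
  with_preserved_rng({
    set.seed(spec$seed)
    strata <- lapply(seq_len(nrow(spec$groups)), function(g) sample_stratum(spec, g))
  })
  sub <- do.call(rbind, strata)
  sub$weight_kg <- sub$bmi * sub$height_m^2
  sub$lbm_kg <- compute_lbm(sub$weight_kg, sub$bmi, sub$sex)
  sub$bmi_group <- assign_bmi_group(sub$bmi)
  sub$age_group <- assign_age_group(sub$age_years)
  sub <- cbind(subject_id = sprintf("S%05d", seq_len(nrow(sub))), sub)
  sub <- sub[, c("subject_id", "age_years", "sex", "height_m", "weight_kg",
                 "bmi", "lbm_kg", "bmi_group", "age_group")]
  rownames(sub) <- NULL
  structure(sub,
    stratify_by = spec$stratify_by, seed = spec$seed,
    class = c("igsim_subjects", "data.frame")
  )
}

#' Read and write subject tables
#'
#' CSV dialect: UTF-8, '.' decimal separator, header `subject_id, age_years,
#' sex, height_m, weight_kg, bmi, lbm_kg, bmi_group, age_group`. Reading a
#' user-supplied table bypasses generation; derived columns are validated and
#' recomputed if absent.
#'
#' @param subjects An `igsim_subjects` data.frame.
#' @param path File path.
#' @param stratify_by For [read_subjects()]: which label column is the
#'   stratification variable (`"bmi"` or `"age"`).
#' @return [read_subjects()] returns an `igsim_subjects` data.frame.
#' @export
write_subjects <- function(subjects, path) {
  cols <- c("subject_id", "age_years", "sex", "height_m", "weight_kg",
            "bmi", "lbm_kg", "bmi_group", "age_group")
  utils::write.csv(as.data.frame(subjects)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path, stratify_by = c("bmi", "age")) {
  stratify_by <- match.arg(stratify_by)
  sub <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "sex", "height_m", "weight_kg")
  if (!all(need %in% names(sub))) {
    stopf("subject CSV must contain columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(sub$bmi)) sub$bmi <- compute_bmi(sub$weight_kg, sub$height_m)
  if (max(abs(sub$bmi - sub$weight_kg / sub$height_m^2) / sub$bmi) > 1e-9) {
    stopf("`bmi` column inconsistent with weight/height^2")
  }
  if (is.null(sub$lbm_kg)) sub$lbm_kg <- compute_lbm(sub$weight_kg, sub$bmi, sub$sex)
  if (is.null(sub$bmi_group)) sub$bmi_group <- assign_bmi_group(sub$bmi)
  if (is.null(sub$age_group)) sub$age_group <- assign_age_group(sub$age_years)
  structure(sub, stratify_by = stratify_by,
            class = c("igsim_subjects", "data.frame"))
}
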