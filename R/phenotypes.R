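#' Fatty liver index (FLI)
#'
#' Computes the fatty liver index, a logistic score in (0, 100) built from
#' circulating triglycerides, body mass index, gamma-glutamyltransferase and
#' waist circumference:
#' \deqn{L = 0.953\,\ln(TG) + 0.139\,BMI + 0.718\,\ln(GGT) + 0.053\,waist - 15.745}
#' \deqn{FLI = 100\, e^L / (1 + e^L).}
#' Values above 60 are conventionally taken to suggest hepatic steatosis.
#'
#' The original index was derived with triglycerides in mg/dl; supply
#' `tg_unit = "mmol/l"` to convert (x 88.57) before evaluation.
#'
#' @param triglycerides Serum triglycerides (mg/dl by default), strictly positive.
#' @param bmi Body mass index in kg/m^2, strictly positive.
#' @param ggt Gamma-glutamyltransferase in U/l, strictly positive.
#' @param waist Waist circumference in cm, strictly positive.
#' @param tg_unit Unit of `triglycerides`; `"mg/dl"` (default) or `"mmol/l"`.
#' @return Numeric vector of FLI scores in (0, 100). Missing inputs propagate.
#' @examples
#' fatty_liver_index(100, 25, 30, 94)
#' @export
fatty_liver_index <- function(triglycerides, bmi, ggt, waist,
                              tg_unit = c("mg/dl", "mmol/l")) {
  tg_unit <- match.arg(tg_unit)
  check_numeric(triglycerides, "triglycerides", lower = 0, strict_lower = TRUE,
                allow_na = TRUE)
  check_numeric(bmi, "bmi", lower = 0, strict_lower = TRUE, allow_na = TRUE)
  check_numeric(ggt, "ggt", lower = 0, strict_lower = TRUE, allow_na = TRUE)
  check_numeric(waist, "waist", lower = 0, strict_lower = TRUE, allow_na = TRUE)
  tg <- if (tg_unit == "mmol/l") triglycerides * 88.57 else triglycerides
  l <- 0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) + 0.053 * waist - 15.745
  100 * plogis(l)
}

#' Rank-based inverse-normal transformation
#'
#' Maps a skewed variable onto standard-normal scores through its ranks,
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))}, with the Blom offset \eqn{c = 3/8}
#' by default. Ties receive their average rank and missing values propagate.
#' The transform is monotone (rank-preserving) and produces scores with mean
#' approximately zero.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @param offset Rank offset `c`; 3/8 (Blom, default), 1/2 (Tukey) or 0.
#' @return Numeric vector of normal scores, same length and NA pattern as `x`.
#' @examples
#' inverse_normal_transform(c(5, 1, 9, 2, 40))
#' @export
inverse_normal_transform <- function(x, offset = 3/8) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3) stop("inverse_normal_transform needs at least 3 non-missing values")
  v <- x[obs]
  if (length(unique(v)) == 1L)
    stop("all values identical: no rank information to transform")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Alcohol intake in drinks per day (mediation covariate)
#'
#' Categorises daily alcohol intake into the three-level covariate used in the
#' mediation models: no alcohol, up to one standard drink per day, or more than
#' one. A standard drink is 12 g of pure ethanol; the boundary of exactly one
#' drink falls in the middle category.
#'
#' @param grams_per_day Non-negative daily intake of pure ethanol in grams.
#' @return Factor with levels `none`, `up_to_one`, `more_than_one`.
#' @examples
#' categorize_alcohol_mediation(c(0, 6, 12, 30))
#' @export
categorize_alcohol_mediation <- function(grams_per_day) {
  check_numeric(grams_per_day, "grams_per_day", lower = 0, allow_na = TRUE)
  lv <- c("none", "up_to_one", "more_than_one")
  out <- ifelse(grams_per_day == 0, "none",
         ifelse(grams_per_day <= 12, "up_to_one", "more_than_one"))
  factor(out, levels = lv)
}

#' Weekly alcohol consumption class
#'
#' Classifies drinkers as none / moderate / excess using sex-specific weekly
#' limits: moderate consumption is at most 350 g of pure ethanol per week for
#' females and 420 g per week for males (boundaries inclusive); anything above
#' is excess. Weekly grams are 7 x daily grams.
#'
#' @param grams_per_day Non-negative daily intake of pure ethanol in grams.
#' @param sex Sex per sample: `"female"`/`"male"`, or binary numeric with
#'   1 = female, 0 = male.
#' @return Factor with levels `none`, `moderate`, `excess`.
#' @examples
#' classify_alcohol_consumption(c(0, 50, 61), c("male", "female", "male"))
#' @export
classify_alcohol_consumption <- function(grams_per_day, sex) {
  check_numeric(grams_per_day, "grams_per_day", lower = 0, allow_na = TRUE)
  female <- sex_to_female(sex)
  if (length(female) == 1L) female <- rep(female, length(grams_per_day))
  if (length(female) != length(grams_per_day))
    stop("'sex' must have length 1 or length(grams_per_day)")
  weekly <- 7 * grams_per_day
  limit <- ifelse(female, 350, 420)
  out <- ifelse(weekly == 0, "none", ifelse(weekly <= limit, "moderate", "excess"))
  factor(out, levels = c("none", "moderate", "excess"))
}

# Normalise the accepted sex encodings to a logical "is female".
sex_to_female <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.character(sex)) {
    s <- tolower(sex)
    if (!all(s %in% c("female", "male", "f", "m"), na.rm = TRUE))
      stop("unknown sex code; use 'female'/'male' or 0/1 (1 = female)")
    return(s %in% c("female", "f"))
  }
  if (is.numeric(sex) || is.logical(sex)) {
    if (!all(sex %in% c(0, 1), na.rm = TRUE))
      stop("unknown sex code; use 'female'/'male' or 0/1 (1 = female)")
    return(sex == 1)
  }
  stop("unknown sex code; use 'female'/'male' or 0/1 (1 = female)")
}

#' BMI stratum for stratified mediation
#'
#' Splits participants at 25 kg/m^2: BMI below 25 is `normal_weight`, 25 and
#' above is `overweight_obese`.
#'
#' @param bmi Body mass index in kg/m^2, strictly positive.
#' @return Factor with levels `normal_weight`, `overweight_obese`.
#' @examples
#' bmi_strata(c(24.9, 25, 40))
#' @export
bmi_strata <- function(bmi) {
  check_numeric(bmi, "bmi", lower = 0, strict_lower = TRUE, allow_na = TRUE)
  factor(ifelse(bmi < 25, "normal_weight", "overweight_obese"),
         levels = c("normal_weight", "overweight_obese"))
}

#' Derive analysis phenotypes for a cohort
#'
#' Appends the derived analysis variables to a simulated cohort (or to a plain
#' per-sample table with the same columns): the fatty liver index, the
#' inverse-normal transformed liver variables (`ggt_int`, `alt_int`, `ast_int`,
#' `fli_int`), the three-level drinks-per-day alcohol covariate, the weekly
#' alcohol consumption class and the BMI stratum.
#'
#' @param x A `sim_cohort` (see [simulate_cohort()]) or a data.frame with
#'   columns `ggt`, `alt`, `ast`, `triglycerides` (mg/dl), `bmi`, `waist`,
#'   `alcohol_gday` and `sex`.
#' @param int_offset Rank offset for [inverse_normal_transform()].
#' @return The input with a phenotype table extended by the derived columns
#'   (for a cohort, `x$phenotypes`; for a data.frame, the data.frame itself).
#' @export
derive_phenotypes <- function(x, int_offset = 3/8) {
  if (inherits(x, "sim_cohort")) {
    tab <- cbind(x$phenotypes,
                 x$covariates[c("triglycerides", "bmi", "waist", "alcohol_gday", "sex")])
    der <- derive_phenotypes(tab, int_offset = int_offset)
    keep <- setdiff(names(der), c("triglycerides", "bmi", "waist", "alcohol_gday", "sex"))
    x$phenotypes <- der[keep]
    return(x)
  }
  stopifnot(is.data.frame(x))
  need <- c("ggt", "alt", "ast", "triglycerides", "bmi", "waist", "alcohol_gday", "sex")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  x$fli <- fatty_liver_index(x$triglycerides, x$bmi, x$ggt, x$waist)
  x$ggt_int <- inverse_normal_transform(x$ggt, offset = int_offset)
  x$alt_int <- inverse_normal_transform(x$alt, offset = int_offset)
  x$ast_int <- inverse_normal_transform(x$ast, offset = int_offset)
  x$fli_int <- inverse_normal_transform(x$fli, offset = int_offset)
  x$alcohol_drinks_cat <- categorize_alcohol_mediation(x$alcohol_gday)
  x$alcohol_class <- classify_alcohol_consumption(x$alcohol_gday, x$sex)
  x$bmi_stratum <- bmi_strata(x$bmi)
  x
}
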