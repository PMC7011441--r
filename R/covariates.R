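#' Encode raw participant characteristics as analysis covariates
#'
#' Ages are grouped 16-24 / 25-34 / 35-49 / 50+; `Mixed` ethnicity is
#' combined into `Other`; occupation is coded to the three NS-SEC classes
#' (higher managerial/professional, intermediate, routine/manual) with an
#' additional economically-inactive class covering the unemployed, those
#' unable to work, retired people, home carers and students.
#'
#' @param raw Data frame with any of: `age` (years, >= 16), `ethnicity`
#'   (`White/Black/Asian/Mixed/Other`), `occupation` (one of
#'   `higher_managerial`, `professional`, `intermediate`, `routine`,
#'   `manual`, `unemployed`, `disabled`, `retired`, `home_carer`,
#'   `student`), `working` and `studying` logicals.  Already-encoded
#'   columns pass through unchanged.
#' @return `raw` with `age_group`, `ethnic_group`, `nssec`,
#'   `working_studying` factors appended.  Unknown categories are an error
#'   listing the offending values.
#' @export
encode_covariates <- function(raw) {
  out <- raw
  if ("age" %in% names(raw)) {
    if (any(raw$age < 16, na.rm = TRUE))
      stop("ages below 16 are out of scope", call. = FALSE)
    out$age_group <- cut(raw$age, c(16, 25, 35, 50, Inf), right = FALSE,
                         labels = c("16-24", "25-34", "35-49", "50+"))
  }
  if ("ethnicity" %in% names(raw)) {
    valid <- c("White", "Black", "Asian", "Mixed", "Other")
    bad <- setdiff(unique(raw$ethnicity), c(valid, NA))
    if (length(bad))
      stop("unknown ethnicity value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    e <- as.character(raw$ethnicity)
    e[e == "Mixed"] <- "Other"
    out$ethnic_group <- factor(e, c("White", "Black", "Asian", "Other"))
  }
  if ("occupation" %in% names(raw)) {
    map <- c(higher_managerial = "higher_managerial_professional",
             professional = "higher_managerial_professional",
             intermediate = "intermediate",
             routine = "routine_manual", manual = "routine_manual",
             unemployed = "economically_inactive",
             disabled = "economically_inactive",
             retired = "economically_inactive",
             home_carer = "economically_inactive",
             student = "economically_inactive")
    bad <- setdiff(unique(raw$occupation), c(names(map), NA))
    if (length(bad))
      stop("unknown occupation value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    out$nssec <- factor(map[as.character(raw$occupation)],
                        c("higher_managerial_professional", "intermediate",
                          "routine_manual", "economically_inactive"))
  }
  if (all(c("working", "studying") %in% names(raw)))
    out$working_studying <- raw$working | raw$studying
  out
}
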