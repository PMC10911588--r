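#' Reference patient
#'
#' @param weight Body weight in kg (cohort average 65).
#' @param bsa Body surface area in m^2 (cohort average 1.72).
#' @export
patient <- function(weight = 65, bsa = 1.72) {
  stopifnot(weight > 0, bsa > 0)
  structure(list(weight = weight, bsa = bsa), class = "patient")
}

#' Drug unit price
#'
#' @param name Drug name.
#' @param unit_cost Cost in USD of one unit (vial or tablet).
#' @param unit_size mg per unit.
#' @param currency Currency tag.
#' @export
drug_price <- function(name, unit_cost, unit_size, currency = "USD") {
  stopifnot(unit_cost >= 0, unit_size > 0)
  structure(list(name = name, unit_cost = unit_cost, unit_size = unit_size,
                 currency = currency), class = "drug_price")
}

#' Dosing rule within a 21-day model cycle
#'
#' @param drug Drug name (must match a [drug_price()]).
#' @param dose Dose per administration, in mg, mg/kg or mg/m^2 per `basis`.
#' @param basis `"fixed"`, `"per_kg"` or `"per_m2"`.
#' @param admin_per_cycle Administrations per model cycle; may be
#'   fractional when the regimen schedule differs from the cycle length
#'   (e.g. 1.5 for a 14-day schedule inside a 21-day cycle).
#' @param state Health state the rule applies to, `"PFS"` or `"PD"`.
#' @param rounding `"vial"` (round the per-administration requirement up to
#'   whole units, no vial sharing) or `"exact"` (tablet counts; exact).
#' @export
regimen_rule <- function(drug, dose, basis = c("fixed", "per_kg", "per_m2"),
                         admin_per_cycle = 1, state = c("PFS", "PD"),
                         rounding = c("vial", "exact")) {
  basis <- match.arg(basis); state <- match.arg(state)
  rounding <- match.arg(rounding)
  stopifnot(dose >= 0, admin_per_cycle >= 0)
  structure(list(drug = drug, dose = dose, basis = basis,
                 admin_per_cycle = admin_per_cycle, state = state,
                 rounding = rounding), class = "regimen_rule")
}

#' Drug acquisition cost per model cycle
#'
#' For each rule the per-administration requirement in mg is resolved
#' against the patient (fixed, per kg, or per m^2), converted to units of
#' the priced pack (vials rounded up, tablets exact), and multiplied by the
#' administrations per cycle.
#'
#' @param rules List of [regimen_rule()]s.
#' @param prices List of [drug_price()]s.
#' @param pat A [patient()].
#' @return Cost in USD per cycle.
#' @export
drug_cost_per_cycle <- function(rules, prices, pat = patient()) {
  price_of <- function(drug) {
    for (p in prices) if (p$name == drug) return(p)
    stop("no price configured for drug '", drug, "'")
  }
  total <- 0
  for (r in rules) {
    p <- price_of(r$drug)
    mg <- switch(r$basis, fixed = r$dose, per_kg = r$dose * pat$weight,
                 per_m2 = r$dose * pat$bsa)
    units <- if (r$rounding == "vial") ceiling(mg / p$unit_size) else mg / p$unit_size
    total <- total + units * p$unit_cost * r$admin_per_cycle
  }
  total
}

#' Expected one-off adverse-event management cost
#'
#' `sum(incidence * cost)` over the included grade >= 3 adverse events,
#' applied once at model entry.
#'
#' @param items Data frame with columns `incidence` (in `[0, 1]`) and
#'   `cost` (USD), one row per adverse event.
#' @export
expected_ae_cost <- function(items) {
  if (is.null(items) || nrow(items) == 0) return(0)
  stopifnot(all(items$incidence >= 0 & items$incidence <= 1),
            all(items$cost >= 0))
  sum(items$incidence * items$cost)
}

#' Health-state utilities
#'
#' @param u_pfs Utility per year in the progression-free state (0.76).
#' @param u_pd Utility per year in the progressed state (0.68). Death is 0.
#' @export
utility_set <- function(u_pfs = 0.76, u_pd = 0.68) {
  if (!(0 <= u_pd && u_pd <= u_pfs && u_pfs <= 1)) {
    stop("need 0 <= u_pd <= u_pfs <= 1")
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_death = 0), class = "utility_set")
}

#' Per-arm economic inputs
#'
#' @param c_pfs_cycle First-line drug cost per cycle in PFS (USD).
#' @param c_pd_cycle Second-line regimen cost per cycle in PD (USD).
#' @param c_followup Follow-up cost per cycle, all alive states (USD).
#' @param one_off_ae_cost Expected adverse-event cost at entry (USD).
#' @param utilities A [utility_set()].
#' @param currency Currency tag; arms with different tags cannot be compared.
#' @export
arm_economics <- function(c_pfs_cycle, c_pd_cycle, c_followup,
                          one_off_ae_cost, utilities = utility_set(),
                          currency = "USD") {
  stopifnot(c_pfs_cycle >= 0, c_pd_cycle >= 0, c_followup >= 0,
            one_off_ae_cost >= 0, inherits(utilities, "utility_set"))
  structure(list(c_pfs_cycle = c_pfs_cycle, c_pd_cycle = c_pd_cycle,
                 c_followup = c_followup, one_off_ae_cost = one_off_ae_cost,
                 utilities = utilities, currency = currency),
            class = "arm_economics")
}

# ---- parameter table -------------------------------------------------------

#' Read a model parameter table
#'
#' The table mirrors the published parameter ledger: one row per model
#' input with columns `category, name, arm, value, low, high, distribution,
#' unit_size, source`. The packaged copy is returned by
#' [default_parameter_table()].
#'
#' @param path CSV path.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  need <- c("category", "name", "arm", "value", "low", "high",
            "distribution", "unit_size", "source")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  tab$arm[is.na(tab$arm)] <- ""
  tab
}

#' Packaged base-case parameter table
#'
#' @export
default_parameter_table <- function() {
  read_parameter_table(system.file("extdata", "parameter_table.csv",
                                   package = "psmcea", mustWork = TRUE))
}

# fetch one row; descriptive error naming the missing row
.param_row <- function(tab, category, name, arm = "") {
  hit <- tab$category == category & tab$name == name &
    (tab$arm == arm | (arm != "" & tab$arm == ""))
  if (!any(hit)) {
    stop("parameter table is missing row category='", category,
         "', name='", name, "', arm='", arm, "'")
  }
  tab[which(hit)[1], ]
}

.param_num <- function(tab, category, name, arm = "") {
  as.numeric(.param_row(tab, category, name, arm)$value)
}

#' Survival model for one arm/endpoint from the parameter table
#'
#' @param tab Parameter table (see [read_parameter_table()]).
#' @param arm Arm label, e.g. `"tislelizumab"`.
#' @param endpoint `"os"` or `"pfs"`.
#' @export
model_from_table <- function(tab, arm, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  fam <- .param_row(tab, "survival", paste0(endpoint, "_family"), arm)$value
  pn <- .family_params[[fam]]
  vals <- vapply(tolower(pn), function(p)
    .param_num(tab, "survival", paste0(endpoint, "_", p), arm), numeric(1))
  psm_model(fam, stats::setNames(vals, pn))
}

#' Default dosing regimens
#'
#' First line: Tislelizumab 200 mg IV once per 21-day cycle, or Sorafenib
#' 400 mg orally twice daily (42 doses per cycle). Second line for both
#' arms, applied to all progressed-disease occupancy: Camrelizumab 200 mg
#' once per 21-day cycle plus FOLFOX4 on its 14-day schedule (1.5
#' schedules per cycle): oxaliplatin 85 mg/m^2 day 1, calcium folinate
#' 200 mg/m^2 days 1-2, fluorouracil 400 mg/m^2 bolus + 600 mg/m^2
#' infusion days 1-2.
#'
#' @param arm `"tislelizumab"` or `"sorafenib"` (selects the first line).
#' @return List with `pfs` and `pd` rule lists.
#' @export
default_regimens <- function(arm = c("tislelizumab", "sorafenib")) {
  arm <- match.arg(arm)
  pfs <- if (arm == "tislelizumab") {
    list(regimen_rule("tislelizumab", 200, "fixed", 1, "PFS", "vial"))
  } else {
    list(regimen_rule("sorafenib", 400, "fixed", 42, "PFS", "exact"))
  }
  pd <- list(
    regimen_rule("camrelizumab", 200, "fixed", 1, "PD", "vial"),
    regimen_rule("oxaliplatin", 85, "per_m2", 1.5, "PD", "vial"),
    regimen_rule("calcium_folinate", 200, "per_m2", 3, "PD", "vial"),
    regimen_rule("fluorouracil", 1000, "per_m2", 3, "PD", "vial")
  )
  list(pfs = pfs, pd = pd)
}

.ae_names <- function(tab) unique(tab$name[tab$category == "cost_ae"])

#' Assemble the economic inputs of one arm from the parameter table
#'
#' Every number is traceable to a table row: first-line and second-line
#' cycle costs from the drug-price rows and [default_regimens()], per-cycle
#' follow-up cost, the expected one-off adverse-event cost from the
#' arm-specific incidence rows and shared management-cost rows, and the
#' health-state utilities.
#'
#' @param tab Parameter table.
#' @param arm `"tislelizumab"` or `"sorafenib"`.
#' @param pat A [patient()].
#' @param regimens Dosing rules, defaulting to [default_regimens()].
#' @return An [arm_economics()] object.
#' @export
build_arm_economics <- function(tab, arm, pat = patient(),
                                regimens = default_regimens(arm)) {
  drugs <- tab[tab$category == "cost_drug", ]
  prices <- lapply(seq_len(nrow(drugs)), function(i)
    drug_price(drugs$name[i], as.numeric(drugs$value[i]), drugs$unit_size[i]))
  ae <- data.frame(
    incidence = vapply(.ae_names(tab), function(nm)
      .param_num(tab, "risk_ae", nm, arm), numeric(1)),
    cost = vapply(.ae_names(tab), function(nm)
      .param_num(tab, "cost_ae", nm), numeric(1)))
  arm_economics(
    c_pfs_cycle = drug_cost_per_cycle(regimens$pfs, prices, pat),
    c_pd_cycle = drug_cost_per_cycle(regimens$pd, prices, pat),
    c_followup = .param_num(tab, "cost_followup", "followup"),
    one_off_ae_cost = expected_ae_cost(ae),
    utilities = utility_set(.param_num(tab, "utility", "utility_pfs"),
                            .param_num(tab, "utility", "utility_pd")))
}
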