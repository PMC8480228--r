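LIVESTOCK_SYSTEMS <- c("tmr", "intensive_grazing", "extensive")
INCOME_GROUPS <- c("high", "upper_middle", "lower_middle", "low")

#' Livestock emissions table
#'
#' 2010 livestock CH4 emissions disaggregated by production system (TMR /
#' feedlot, intensive grazing / mixed, extensive) and World Bank income
#' group. The package bundles a clearly-labelled synthetic example table
#' (`gleam_2010_synthetic.csv`) whose TMR total is back-calibrated so the
#' calculator reproduces the published TMR-inhibitor mitigation potential;
#' supply a CSV extract of a real system-level assessment for substantive
#' results.
#'
#' @param system Character vector of production systems (values among
#'   `"tmr"`, `"intensive_grazing"`, `"extensive"`).
#' @param income_group Character vector of income groups (values among
#'   `"high"`, `"upper_middle"`, `"lower_middle"`, `"low"`).
#' @param mt_ch4_2010 Nonnegative emissions in Mt CH4/yr.
#' @return A data frame of class `livestock_table` with unique
#'   (system, income_group) rows.
#' @export
livestock_table <- function(system, income_group, mt_ch4_2010) {
  system <- match.arg(as.character(system), LIVESTOCK_SYSTEMS, several.ok = TRUE)
  income_group <- match.arg(as.character(income_group), INCOME_GROUPS, several.ok = TRUE)
  df <- data.frame(
    system = as.character(system),
    income_group = as.character(income_group),
    mt_ch4_2010 = as.numeric(mt_ch4_2010),
    stringsAsFactors = FALSE
  )
  if (any(df$mt_ch4_2010 < 0)) stop("emissions must be >= 0", call. = FALSE)
  if (anyDuplicated(df[c("system", "income_group")])) {
    stop("(system, income_group) pairs must be unique", call. = FALSE)
  }
  class(df) <- c("livestock_table", "data.frame")
  df
}

#' Read a livestock emissions table from CSV
#'
#' Expects columns `system`, `income_group`, `mt_ch4_2010`.
#'
#' @param path CSV path; defaults to the bundled synthetic example table.
#' @return A [livestock_table()].
#' @export
read_livestock_table <- function(path = system.file("extdata",
                                   "gleam_2010_synthetic.csv",
                                   package = "ch4margin"
                                 )) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  livestock_table(df$system, df$income_group, df$mt_ch4_2010)
}

#' Scale a livestock table to a 2050 baseline
#'
#' Multiplies every row by a growth factor (default 1.3, a 30\% increase
#' from 2010 approximating business-as-usual 2050 emissions).
#'
#' @param table A [livestock_table()].
#' @param growth Growth factor (> 0).
#' @return A [livestock_table()] of scaled emissions.
#' @export
baseline_2050 <- function(table, growth = 1.3) {
  stopifnot(inherits(table, "livestock_table"), growth > 0)
  table$mt_ch4_2010 <- table$mt_ch4_2010 * growth
  table
}

#' Mitigation intervention
#'
#' An intervention applies a fractional emission reduction (`efficacy`) to a
#' subset of (system, income group) cells, each with an adoption fraction.
#'
#' @param name Intervention name.
#' @param systems Applicable production systems.
#' @param income_groups Applicable income groups.
#' @param efficacy Fractional emission reduction in `[0, 1]`.
#' @param adoption Either a single adoption fraction in `[0, 1]` applied to
#'   every applicable cell, or a named vector keyed by income group.
#' @param growth Baseline growth factor to 2050 (default 1.3).
#' @return An object of class `intervention`.
#' @export
intervention <- function(name, systems, income_groups, efficacy, adoption,
                         growth = 1.3) {
  systems <- match.arg(as.character(systems), LIVESTOCK_SYSTEMS, several.ok = TRUE)
  income_groups <- match.arg(as.character(income_groups), INCOME_GROUPS, several.ok = TRUE)
  if (efficacy < 0 || efficacy > 1) stop("efficacy must be in [0, 1]", call. = FALSE)
  if (any(adoption < 0) || any(adoption > 1)) {
    stop("adoption must be in [0, 1]", call. = FALSE)
  }
  if (growth <= 0) stop("growth must be > 0", call. = FALSE)
  if (length(adoption) > 1L || !is.null(names(adoption))) {
    extra <- setdiff(names(adoption), income_groups)
    if (length(extra)) {
      warning(
        "adoption specified for inapplicable income group(s): ",
        paste(extra, collapse = ", "), " (ignored)",
        call. = FALSE
      )
      adoption <- adoption[intersect(names(adoption), income_groups)]
    }
  }
  structure(
    list(
      name = name, systems = systems, income_groups = income_groups,
      efficacy = efficacy, adoption = adoption, growth = growth
    ),
    class = "intervention"
  )
}

#' Read interventions from a YAML file
#'
#' @param path YAML path; defaults to the bundled schedules for emerging
#'   technologies (inhibitors, vaccine, low-emissions breeding, seaweed).
#' @return A named list of [intervention()] objects.
#' @export
read_interventions <- function(path = system.file("extdata",
                                 "interventions.yaml",
                                 package = "ch4margin"
                               )) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(nm) {
    e <- y[[nm]]
    adoption <- unlist(e$adoption)
    intervention(
      name = nm, systems = unlist(e$systems),
      income_groups = unlist(e$income_groups),
      efficacy = e$efficacy, adoption = adoption,
      growth = if (is.null(e$growth)) 1.3 else e$growth
    )
  })
  names(out) <- names(y)
  out
}

#' Global mitigation potential of an intervention in 2050
#'
#' Sums `emissions_2010 x growth x efficacy x adoption` over the applicable
#' (system, income group) cells of the table.
#'
#' @param table A [livestock_table()] of 2010 emissions.
#' @param intervention An [intervention()].
#' @return Mitigation potential in Mt CH4/yr (2050).
#' @examples
#' tab <- livestock_table(
#'   c("tmr", "extensive"), c("high", "low"), c(3, 7)
#' )
#' iv <- intervention("demo", c("tmr", "extensive"),
#'   c("high", "low"),
#'   efficacy = 0.2, adoption = 1
#' )
#' mitigation_potential(tab, iv) # 1.3 * (3 + 7) * 0.2
#' @export
mitigation_potential <- function(table, intervention) {
  stopifnot(inherits(table, "livestock_table"), inherits(intervention, "intervention"))
  iv <- intervention
  applicable <- table$system %in% iv$systems & table$income_group %in% iv$income_groups
  rows <- table[applicable, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(0)
  }
  adopt <- if (is.null(names(iv$adoption))) {
    rep(iv$adoption[1L], nrow(rows))
  } else {
    a <- iv$adoption[rows$income_group]
    a[is.na(a)] <- 0
    as.numeric(a)
  }
  sum(rows$mt_ch4_2010 * iv$growth * iv$efficacy * adopt)
}

#' Subtract a ramped mitigation wedge from a CH4 pathway
#'
#' Applies a mitigation potential to a business-as-usual pathway as a wedge
#' ramping linearly from zero at `ramp_start` to the full potential at
#' `full_year`, held constant afterwards. The result is clipped at zero
#' (with a warning) if the wedge would exceed the pathway.
#'
#' @param bau_ch4 A CH4 [emissions_pathway()].
#' @param potential Mitigation potential in Mt CH4/yr.
#' @param ramp_start First year of deployment (default 2025).
#' @param full_year Year of full deployment (default 2050).
#' @return An [emissions_pathway()].
#' @export
apply_to_pathway <- function(bau_ch4, potential, ramp_start = 2025,
                             full_year = 2050) {
  stopifnot(inherits(bau_ch4, "emissions_pathway"), potential >= 0, full_year > ramp_start)
  y <- bau_ch4$years
  wedge <- potential * pmin(pmax((y - ramp_start) / (full_year - ramp_start), 0), 1)
  out <- bau_ch4$values - wedge
  if (any(out < 0)) {
    warning("mitigation wedge exceeds the pathway; clipping at zero", call. = FALSE)
    out <- pmax(out, 0)
  }
  emissions_pathway("ch4_livestock", y, out,
    label = paste0(bau_ch4$label, " - wedge ", signif(potential, 3), " Mt")
  )
}
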