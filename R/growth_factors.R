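#' Define a growth factor's transport, decay and potency parameters
#'
#' A growth factor record bundles the physical constants needed to simulate
#' its distribution in the culture compartment: the concentration at which it
#' is supplemented into media, its molecular weight, its free-solution
#' diffusivity, its half-life in culture media, and the half-maximal
#' effective concentration (EC50) used as the bioactivity threshold.
#'
#' @param name Factor label, e.g. `"VEGF"`.
#' @param supplemented_conc Supplemented media concentration (ng/mL).
#' @param molecular_weight Molecular weight (g/mol).
#' @param diffusivity Diffusion coefficient in media (um^2/s).
#' @param half_life Decay half-life in culture media (s); must be finite.
#' @param ec50 Half-maximal effective concentration (ng/mL).
#' @return An object of class `growth_factor`.
#' @examples
#' vegf <- growth_factor("VEGF", 5, 38200, 200, 3600, 1.7)
#' decay_rate(vegf$half_life)
#' @export
growth_factor <- function(name, supplemented_conc, molecular_weight,
                          diffusivity, half_life, ec50) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- c(supplemented_conc = supplemented_conc,
            molecular_weight = molecular_weight,
            diffusivity = diffusivity,
            half_life = half_life,
            ec50 = ec50)
  if (!all(is.finite(vals)))
    stop("all growth factor parameters must be finite numbers", call. = FALSE)
  if (any(vals <= 0))
    stop("growth factor parameters must be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  structure(list(name = name,
                 supplemented_conc = as.numeric(supplemented_conc),
                 molecular_weight = as.numeric(molecular_weight),
                 diffusivity = as.numeric(diffusivity),
                 half_life = as.numeric(half_life),
                 ec50 = as.numeric(ec50)),
            class = "growth_factor")
}

#' @export
print.growth_factor <- function(x, ...) {
  cat(sprintf(
    "<growth_factor> %s: C0 = %g ng/mL, MW = %g g/mol, D = %g um^2/s, t1/2 = %g s, EC50 = %g ng/mL\n",
    x$name, x$supplemented_conc, x$molecular_weight, x$diffusivity,
    x$half_life, x$ec50))
  invisible(x)
}

#' Built-in growth factor parameter table
#'
#' Returns the packaged set of growth factor records covering the stromal
#' (FGF-alpha, EGF, FGF-beta), vascular (IGF-1, VEGF, plus EGF and FGF-beta,
#' which appear in both stromal and vascular media) and adipogenic
#' (dexamethasone, insulin) supplements, with literature-derived
#' supplemented concentrations, diffusivities, half-lives and EC50 values.
#' IBMX is not included: its diffusion and half-life kinetics are not
#' characterised well enough to model.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`name, supplemented_conc, molecular_weight, diffusivity, half_life,
#'   ec50, media_group`).
#' @return A named list of [growth_factor()] objects.
#' @export
default_growth_factors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "growth_factors.csv",
                        package = "gradientchip", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "supplemented_conc", "molecular_weight", "diffusivity",
            "half_life", "ec50")
  if (!all(need %in% names(tab)))
    stop("growth factor table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    growth_factor(tab$name[i], tab$supplemented_conc[i],
                  tab$molecular_weight[i], tab$diffusivity[i],
                  tab$half_life[i], tab$ec50[i]))
  names(out) <- tab$name
  attr(out, "media_group") <- if ("media_group" %in% names(tab))
    stats::setNames(tab$media_group, tab$name) else NULL
  out
}

#' Define a media composition
#'
#' A media composition names which growth factors a reservoir supplies and
#' at what concentration. Factors absent from the map are at zero
#' concentration in that media.
#'
#' @param name Media label (e.g. `"vascular"`, `"stromal"`,
#'   `"adipogenic_initiation"`, `"adipogenic_maturation"`).
#' @param factors Named numeric vector, factor name -> concentration (ng/mL).
#' @param factor_set Named list of [growth_factor()] records; every factor
#'   named in `factors` must have a record here.
#' @return An object of class `media_composition`.
#' @export
media_composition <- function(name, factors,
                              factor_set = default_growth_factors()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(factors)) {
    stopifnot(is.numeric(factors), !is.null(names(factors)),
              all(nzchar(names(factors))))
    if (any(factors < 0))
      stop("media concentrations must be >= 0", call. = FALSE)
    missing <- setdiff(names(factors), names(factor_set))
    if (length(missing))
      stop("no growth factor record for: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, factors = factors),
            class = "media_composition")
}

#' Default media compositions for the gradient co-culture
#'
#' Four media are used across the 31-day protocol: complete stromal (MSC)
#' media, complete vascular (EC) media, adipocyte initiation media and
#' adipocyte maturation media. Each supplies its group's factors at the
#' supplemented concentration recorded in the packaged parameter table;
#' EGF and FGF-beta appear in both stromal and vascular media. The two
#' adipogenic media are proprietary and are approximated here as carrying
#' the modelled adipogenic factors (dexamethasone and insulin) at identical
#' concentrations.
#'
#' @param factor_set Named list of [growth_factor()] records.
#' @return Named list of [media_composition()] objects with elements
#'   `stromal`, `vascular`, `adipogenic_initiation`, `adipogenic_maturation`.
#' @export
default_media <- function(factor_set = default_growth_factors()) {
  conc <- function(fn) {
    fn <- intersect(fn, names(factor_set))
    vapply(factor_set[fn], `[[`, numeric(1), "supplemented_conc")
  }
  adipo <- conc(c("DEX", "Insulin"))
  list(
    stromal = media_composition(
      "stromal", conc(c("FGF-alpha", "EGF", "FGF-beta")), factor_set),
    vascular = media_composition(
      "vascular", conc(c("IGF-1", "VEGF", "EGF", "FGF-beta")), factor_set),
    adipogenic_initiation = media_composition(
      "adipogenic_initiation", adipo, factor_set),
    adipogenic_maturation = media_composition(
      "adipogenic_maturation", adipo, factor_set)
  )
}

#' Concentration of one factor in a media composition
#'
#' @param media A [media_composition()].
#' @param factor Factor name.
#' @return Concentration in ng/mL; 0 if the media does not carry the factor.
#' @export
media_concentration <- function(media, factor) {
  stopifnot(inherits(media, "media_composition"))
  if (factor %in% names(media$factors)) unname(media$factors[[factor]]) else 0
}
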