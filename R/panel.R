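# Reference element panel and class-conditional concentration distributions
# for the eggshell authentication problem. Values are from a reference
# ICP-AES study of Chinese free-range vs caged eggshells (16 elements,
# analytical wavelengths, 3-sigma detection limits, per-class mean (SD) in
# ug/g); the free-range Cd channel is structurally nondetect.

.panel_elements <- c("Zn", "Pb", "Cd", "Co", "Ni", "Fe", "Mn", "Cr",
                     "Mg", "Cu", "Se", "Ca", "Al", "Sr", "Na", "K")

.panel_wavelengths <- c(213.85, 220.35, 226.50, 228.61, 231.60, 238.20,
                        257.61, 267.71, 280.26, 324.75, 361.38, 393.36,
                        396.15, 407.77, 589.60, 766.49)

.panel_dl <- c(0.05, 0.09, 0.03, 0.03, 0.05, 0.04, 0.07, 0.02,
               0.08, 0.07, 0.04, 0.08, 0.10, 0.02, 0.33, 0.76)

.free_mean <- c(1.72, 1.04, 0, 0.22, 0.44, 2.1, 0.67, 0.71,
                6042, 1.56, 4.22, 366310, 71.9, 120.4, 2156, 1850)
.free_sd   <- c(0.39, 0.27, 0, 0.04, 0.12, 0.6, 0.13, 0.28,
                2106, 0.31, 1.68, 46778, 6.5, 24.8, 388, 302)
.caged_mean <- c(2.33, 2.16, 0.34, 0.32, 0.59, 3.2, 1.01, 2.32,
                 5363, 2.13, 2.18, 342560, 88.5, 171.3, 3016, 2305)
.caged_sd   <- c(0.51, 0.19, 0.08, 0.09, 0.10, 1.0, 0.31, 1.03,
                 1849, 0.55, 1.01, 35458, 11.7, 44.6, 612, 226)

# Latent-factor loading angles (degrees) per element for the synthetic
# generator's within-class covariance: factor 1 = shell mineralization
# (dominates Ca, Mg, Sr, Na, K), factor 2 = trace/diet uptake (dominates the
# heavy/trace metals). Fixed a priori; see the methods vignette.
.factor_angles_deg <- c(Zn = 75, Pb = 80, Cd = 85, Co = 70, Ni = 65, Fe = 60,
                        Mn = 55, Cr = 80, Mg = 10, Cu = 70, Se = 50, Ca = 5,
                        Al = 45, Sr = 15, Na = 20, K = 25)

# Producing-area batch sizes per class (reference sampling design);
# used to attach realistic area metadata to synthetic samples.
.area_names <- c("Guizhou", "Henan", "Anhui", "Jiangsu", "Hubei", "Guangxi", "Hunan")
.area_free  <- c(10, 22, 20, 15, 26, 16, 18)   # sums to 127
.area_caged <- c(11, 18, 16, 20, 19, 17, 21)   # sums to 122

#' The 16-element ICP-AES eggshell panel
#'
#' Element symbols in panel (column) order, the analytical emission
#' wavelength used for each, and the per-element detection limit (3 sigma of
#' 11 blank replicates).
#'
#' @return A data frame with columns `element`, `wavelength_nm`, `dl_ug_g`
#'   and class `element_panel`.
#' @export
#' @examples
#' element_panel()
element_panel <- function() {
  panel <- data.frame(
    element = .panel_elements,
    wavelength_nm = .panel_wavelengths,
    dl_ug_g = .panel_dl,
    stringsAsFactors = FALSE
  )
  validate_element_panel(panel)
}

#' Validate an element panel
#'
#' Enforces the panel invariants: exactly 16 uniquely named elements with
#' strictly positive wavelengths and detection limits.
#'
#' @param panel data frame with columns `element`, `wavelength_nm`, `dl_ug_g`.
#' @return The panel, classed `element_panel`, invisibly usable downstream.
#' @export
validate_element_panel <- function(panel) {
  need <- c("element", "wavelength_nm", "dl_ug_g")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort_fmt("panel is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(panel) != 16L) abort_fmt("panel must have exactly 16 elements, got %d", nrow(panel))
  if (anyDuplicated(panel$element)) abort_fmt("panel element symbols must be unique")
  if (any(panel$wavelength_nm <= 0)) abort_fmt("panel wavelengths must be strictly positive")
  if (any(panel$dl_ug_g <= 0)) abort_fmt("panel detection limits must be strictly positive")
  class(panel) <- c("element_panel", "data.frame")
  panel
}

#' Class-conditional element distributions
#'
#' Per-class, per-element mean and SD (ug/g) of the reference concentration
#' table, with a nondetect flag for channels that are always below the
#' detection limit (free-range Cd). Nondetect channels store mean = SD = 0.
#'
#' @return Named list with components `"free-range"` and `"caged"`, each a
#'   data frame with columns `element`, `mean`, `sd`, `nondetect`.
#' @export
#' @examples
#' class_distributions()[["free-range"]]
class_distributions <- function() {
  mk <- function(m, s) {
    d <- data.frame(element = .panel_elements, mean = m, sd = s,
                    nondetect = (m == 0 & s == 0), stringsAsFactors = FALSE)
    validate_class_distribution(d)
  }
  list("free-range" = mk(.free_mean, .free_sd),
       "caged" = mk(.caged_mean, .caged_sd))
}

#' Validate a class-conditional distribution table
#'
#' @param dist data frame with columns `element`, `mean`, `sd`, `nondetect`.
#' @return The validated distribution table.
#' @export
validate_class_distribution <- function(dist) {
  need <- c("element", "mean", "sd", "nondetect")
  missing_cols <- setdiff(need, names(dist))
  if (length(missing_cols)) {
    abort_fmt("distribution is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (any(dist$sd < 0)) abort_fmt("distribution SDs must be non-negative")
  if (any(!is.finite(dist$mean)) || any(!is.finite(dist$sd))) {
    abort_fmt("distribution means/SDs must be finite")
  }
  bad <- dist$nondetect & (dist$mean != 0 | dist$sd != 0)
  if (any(bad)) {
    abort_fmt("nondetect channel(s) must store mean = SD = 0: %s",
              paste(dist$element[bad], collapse = ", "))
  }
  dist
}

#' Read panel and class distributions from a JSON config
#'
#' The package ships its reference configuration at
#' `system.file("extdata", "element_panel.json", package = "eggchem")`;
#' users may supply their own file with the same shape.
#'
#' @param path path to a JSON file with fields `panel` and `distributions`.
#' @return `list(panel = <element_panel>, distributions = <named list>)`.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) abort_fmt("panel config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel <- validate_element_panel(as.data.frame(cfg$panel))
  dists <- lapply(cfg$distributions, function(d) validate_class_distribution(as.data.frame(d)))
  if (!setequal(names(dists), c("free-range", "caged"))) {
    abort_fmt("distributions must be given for classes 'free-range' and 'caged'")
  }
  list(panel = panel, distributions = dists)
}

#' Write a panel configuration JSON
#'
#' @param panel an `element_panel`.
#' @param distributions named list of class distribution tables.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, distributions, path) {
  validate_element_panel(panel)
  lapply(distributions, validate_class_distribution)
  jsonlite::write_json(list(panel = panel, distributions = distributions),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}
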