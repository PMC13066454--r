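#' Define an observation variable (trait)
#'
#' A trait definition carries the measurement unit, the plausibility window
#' used by [apply_range_filter()], and a free-text method note.  The method
#' note is where genebank-specific conventions live (e.g. whether heading date
#' counts days from January 1 or from sowing); values are never converted
#' between conventions.
#'
#' @param code Short trait code, e.g. `"HD"`, `"PH"`, `"TKW"`.
#' @param label Human-readable trait name.
#' @param unit Measurement unit (`"days"`, `"cm"`, `"g"`, ...). Must be
#'   non-empty.
#' @param plausible_min,plausible_max Inclusive plausibility bounds in `unit`;
#'   `plausible_min` must be strictly smaller than `plausible_max`.
#' @param method_note Free text describing the measurement method.
#' @return A `trait_definition` object (a named list).
#' @examples
#' trait_definition("PH", "Plant height", "cm", 5, 250)
#' @export
trait_definition <- function(code, label = code, unit, plausible_min,
                             plausible_max, method_note = "") {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("trait unit must be a non-empty string", call. = FALSE)
  plausible_min <- as.numeric(plausible_min)
  plausible_max <- as.numeric(plausible_max)
  if (!is.finite(plausible_min) || !is.finite(plausible_max) ||
      plausible_min >= plausible_max)
    stop("plausible_min must be strictly smaller than plausible_max",
         call. = FALSE)
  structure(
    list(code = code, label = label, unit = unit,
         plausible_min = plausible_min, plausible_max = plausible_max,
         method_note = method_note),
    class = "trait_definition"
  )
}

#' @export
print.trait_definition <- function(x, ...) {
  cat(sprintf("<trait %s: %s [%s], plausible %g..%g>\n",
              x$code, x$label, x$unit, x$plausible_min, x$plausible_max))
  invisible(x)
}

# Presets for the three core regeneration traits.  The plausibility windows
# are deliberately lax recording-error screens, not biological ranges.
.trait_presets <- list(
  HD = list(code = "HD", label = "Days to heading", unit = "days",
            plausible_min = 50, plausible_max = 250,
            method_note = paste("Days until 50% of plants reached heading",
                                "(BBCH 59); reference day (Jan 1 or sowing)",
                                "varies by genebank and is never converted."),
            mu = 150, sigma2_G = 64, sigma2_A = 16, sigma_e = 5),
  PH = list(code = "PH", label = "Plant height", unit = "cm",
            plausible_min = 5, plausible_max = 250,
            method_note = "Soil surface to top of the ear, awns excluded.",
            mu = 100, sigma2_G = 100, sigma2_A = 25, sigma_e = 7),
  TKW = list(code = "TKW", label = "Thousand kernel weight", unit = "g",
             plausible_min = 5, plausible_max = 100,
             method_note = "Grams per 1000 grains at ~15% grain moisture.",
             mu = 40, sigma2_G = 25, sigma2_A = 4, sigma_e = 3)
)

#' Preset definition for a core trait
#'
#' Returns the built-in [trait_definition()] for one of the three core
#' regeneration traits: heading date (`HD`, days, plausible 50--250), plant
#' height (`PH`, cm, plausible 5--250) and thousand kernel weight (`TKW`, g,
#' plausible 5--100).
#'
#' @param code One of `"HD"`, `"PH"`, `"TKW"`.
#' @return A `trait_definition`.
#' @export
trait_preset <- function(code) {
  p <- .trait_presets[[match.arg(code, names(.trait_presets))]]
  trait_definition(p$code, p$label, p$unit, p$plausible_min, p$plausible_max,
                   p$method_note)
}

#' Catalogue of the core traits as a data frame
#'
#' @return A data frame with one row per core trait and columns
#'   `trait_code`, `trait_label`, `unit`, `plausible_min`, `plausible_max`,
#'   `method_note`.
#' @export
core_traits <- function() {
  do.call(rbind, lapply(.trait_presets, function(p) {
    data.frame(trait_code = p$code, trait_label = p$label, unit = p$unit,
               plausible_min = p$plausible_min, plausible_max = p$plausible_max,
               method_note = p$method_note, stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

# internal: trait catalogue row -> trait_definition
.trait_from_row <- function(row) {
  trait_definition(row$trait_code, row$trait_label, row$unit,
                   row$plausible_min, row$plausible_max, row$method_note)
}

# internal: resolve a trait argument (code string, definition, or NULL) against
# a dataset's catalogue
.resolve_trait <- function(ds, trait) {
  if (inherits(trait, "trait_definition")) return(trait)
  if (is.character(trait) && length(trait) == 1L) {
    hit <- ds$traits[ds$traits$trait_code == trait, , drop = FALSE]
    if (nrow(hit) == 1L) return(.trait_from_row(hit[1L, ]))
    if (trait %in% names(.trait_presets)) return(trait_preset(trait))
    stop(sprintf("trait code '%s' not found in the dataset catalogue", trait),
         call. = FALSE)
  }
  stop("trait must be a trait_definition or a trait code", call. = FALSE)
}
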