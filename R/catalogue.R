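#' The 125-feature morphological catalogue
#'
#' The catalogue covers seven kernel categories with fixed counts: time span
#' (23), PPG amplitude (14), VPG/APG amplitude (10), waveform area (4), power
#' area (15), ratio (43) and slope (16). Exemplar features named in the
#' pulse-wave-analysis literature (crest time `OS-`, `Sc-2-`, `b-2d-2~`,
#' `S+1c-1}/O+1O+1}`, `(b-c-d)/a`, ...) are all present; the remaining slots
#' are the systematic closure of the same patterns over the landmark set.
#' The catalogue ships as a JSON config (`inst/extdata/catalogue.json`) so it
#' is inspectable and editable; [ppg_catalogue()] loads it.
#'
#' ASCII notation conventions: trailing `-` = time span, `^` = curve area,
#' `}` = power area, `~` = slope, `/` = ratio; `+k`/`-k` after a landmark
#' letter = evaluation k derivative levels above/below the landmark's native
#' waveform; a doubled `O` (as in `OO-`) = onset-to-next-onset (full beat).
#'
#' @return List of feature definitions (name, category, notation, kernel,
#'   args).
#' @export
ppg_catalogue <- function() {
  cache <- get0(".catalogue_cache", envir = ppght_env)
  if (!is.null(cache)) return(cache)
  path <- system.file("extdata", "catalogue.json", package = "ppght")
  cat_list <- if (nzchar(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    build_catalogue()  # fallback during development
  }
  assign(".catalogue_cache", cat_list, envir = ppght_env)
  cat_list
}

ppght_env <- new.env(parent = emptyenv())

#' Look up catalogue entries by field notation
#'
#' @param notation Character vector of ASCII notations (e.g. `"Sc-2~"`,
#'   `"(b-c-d)/a"`, `"S+1c-1}/O+1O+1}"`).
#' @return Character vector of canonical feature names; `NA` where the
#'   notation matches no entry.
#' @export
ppg_feature_lookup <- function(notation) {
  cat_list <- ppg_catalogue()
  nots <- vapply(cat_list, `[[`, "", "notation")
  names_ <- vapply(cat_list, `[[`, "", "name")
  names_[match(notation, nots)]
}

#' Category counts of the catalogue
#' @return Named integer vector over the seven categories.
#' @export
catalogue_counts <- function() {
  cats <- vapply(ppg_catalogue(), `[[`, "", "category")
  table(factor(cats, levels = c("time_span", "ppg_amplitude", "vpg_apg",
                                "waveform_area", "power_area", "ratio", "slope")))
}

# ---- construction ---------------------------------------------------------

ref_notation <- function(ref) sub("^O2", "O", ref)

# Build the full 125-entry catalogue. Kernel args use landmark refs with
# level-shift tags ("c-2" = APG c wave read on the PPG); "O2" is the next
# beat's onset.
build_catalogue <- function() {
  entries <- list()
  add <- function(name, category, notation, kernel, args) {
    entries[[length(entries) + 1L]] <<-
      list(name = name, category = category, notation = notation,
           kernel = kernel, args = args)
  }
  span <- function(from, to) {
    add(paste0("span_", from, "_", to), "time_span",
        paste0(ref_notation(from), ref_notation(to), "-"),
        "span", list(from = from, to = to))
  }
  amp <- function(ref, category = "ppg_amplitude") {
    add(paste0("amp_", ref), category, ref, "amp", list(ref = ref))
  }
  amp_ratio <- function(num, den, category = "ppg_amplitude") {
    add(paste0("amp_", num, "__over__amp_", den), category,
        paste0(num, "/", den), "ratio",
        list(num = paste0("amp_", num), den = paste0("amp_", den)))
  }
  area <- function(from, to) {
    add(paste0("area_", from, "_", to), "waveform_area",
        paste0(ref_notation(from), ref_notation(to), "^"),
        "area", list(from = from, to = to))
  }
  pw <- function(t1, t2, level) {
    nm <- paste0("pow_", lab_ascii(t1, level), "_", lab_ascii(t2, level))
    add(nm, "power_area",
        paste0(lab_ascii(t1, level), lab_ascii(t2, level), "}"),
        "pow", list(t1 = t1, t2 = t2, level = level))
  }
  slope <- function(from, to) {
    add(paste0("slope_", from, "_", to), "slope",
        paste0(ref_notation(from), ref_notation(to), "~"),
        "slope", list(from = from, to = to))
  }
  comb <- function(labels) {
    body <- paste(labels, collapse = "-")
    add(paste0("comb_", body, "__over__a"), "ratio",
        paste0("(", body, ")/a"), "comb", list(num = labels, den = "a"))
  }
  rat <- function(num, den, notation) {
    add(paste0(num, "__over__", den), "ratio", notation, "ratio",
        list(num = num, den = den))
  }

  # --- time spans (23)
  for (to in c("S", "N", "D", "w-1", "x-1", "y-1", "z-1",
               "a-2", "b-2", "c-2", "d-2", "e-2")) span("O", to)
  for (to in c("N", "D", "c-2", "d-2", "e-2", "O2")) span("S", to)
  span("N", "D"); span("b-2", "c-2"); span("b-2", "d-2"); span("a-2", "e-2")
  span("O", "O2")

  # --- PPG amplitudes (14)
  for (r in c("S", "N", "D", "w-1", "a-2", "b-2", "c-2", "d-2", "e-2")) amp(r)
  for (r in c("N", "D", "w-1", "b-2", "c-2")) amp_ratio(r, "S")

  # --- VPG/APG amplitudes (10)
  for (r in c("a", "b", "c", "d", "e", "w", "x", "y", "z", "c-1")) amp(r, "vpg_apg")

  # --- waveform areas (4)
  area("O", "S"); area("S", "O2"); area("O", "O2"); area("O", "c-2")

  # --- power areas (15)
  pw("O", "S", 0L); pw("S", "O2", 0L); pw("O", "O2", 0L)
  pw("O", "O2", 1L); pw("w", "S", 1L); pw("S", "c", 1L); pw("S", "d", 1L); pw("O", "w", 1L)
  pw("O", "O2", 2L); pw("S", "c", 2L); pw("a", "b", 2L); pw("b", "c", 2L)
  pw("b", "d", 2L); pw("a", "e", 2L); pw("c", "e", 2L)

  # --- slopes (16)
  for (p in list(c("O", "S"), c("S", "N"), c("S", "D"), c("N", "D"), c("S", "O2"),
                 c("S", "c-2"), c("S", "d-2"), c("S", "e-2"),
                 c("b-2", "c-2"), c("b-2", "d-2"), c("c-2", "d-2"),
                 c("O", "w-1"), c("O", "a-2"), c("a-2", "b-2"),
                 c("d-2", "e-2"), c("O", "c-2"))) slope(p[1L], p[2L])

  # --- ratios (43)
  # named exemplars
  rat("span_O_S", "span_O_O2", "OS-/OO-")
  rat("area_O_S", "area_O_O2", "OS^/OO^")
  rat("area_O_c-2", "area_O_O2", "Oc-2^/OO^")
  rat("pow_S+1_c-1", "pow_O+1_O+1", "S+1c-1}/O+1O+1}")
  rat("pow_S+1_d-1", "pow_O+1_O+1", "S+1d-1}/O+1O+1}")
  rat("pow_w_S+1", "pow_O+1_O+1", "wS+1}/O+1O+1}")
  rat("pow_S+2_c", "pow_O+2_O+2", "S+2c}/O+2O+2}")
  amp_ratio("c-1", "w", "ratio")
  for (r in c("b", "c", "d", "e")) amp_ratio(r, "a", "ratio")
  comb(c("b", "c", "d", "e")); comb(c("b", "c", "d"))
  # span closure: every span over the beat period
  span_names <- c("span_O_N", "span_O_D", "span_O_w-1", "span_O_x-1", "span_O_y-1",
                  "span_O_z-1", "span_O_a-2", "span_O_b-2", "span_O_c-2",
                  "span_O_d-2", "span_O_e-2", "span_S_N", "span_S_D", "span_S_c-2",
                  "span_S_d-2", "span_S_e-2", "span_S_O2", "span_N_D",
                  "span_b-2_c-2", "span_b-2_d-2", "span_a-2_e-2")
  for (s in span_names) {
    body <- sub("^span_", "", s)
    parts <- strsplit(body, "_", fixed = TRUE)[[1L]]
    rat(s, "span_O_O2",
        paste0(ref_notation(parts[1L]), ref_notation(parts[2L]), "-/OO-"))
  }
  rat("area_S_O2", "area_O_O2", "SO^/OO^")
  rat("pow_O_S", "pow_O_O", "OS}/OO}")
  rat("pow_S_O", "pow_O_O", "SO}/OO}")
  rat("pow_O+1_w", "pow_O+1_O+1", "O+1w}/O+1O+1}")
  rat("pow_b_c", "pow_O+2_O+2", "bc}/O+2O+2}")
  rat("pow_b_d", "pow_O+2_O+2", "bd}/O+2O+2}")
  rat("pow_a_b", "pow_O+2_O+2", "ab}/O+2O+2}")
  amp_ratio("d-2", "S", "ratio")

  entries
}

# Canonical operand label inside power-area names and notations: the
# landmark letter (O2 rendered as the conventional doubled O) plus the level
# shift relative to its native waveform.
lab_ascii <- function(t, level) {
  d <- level - LANDMARK_LEVEL[[t]]
  nt <- ref_notation(t)
  if (d == 0L) nt else paste0(nt, ifelse(d > 0, "+", ""), d)
}

#' Write the catalogue config to a JSON file
#'
#' Maintainer helper used to (re)generate `inst/extdata/catalogue.json`.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogue_json <- function(path) {
  jsonlite::write_json(build_catalogue(), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
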