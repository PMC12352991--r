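#' Parse FDI (ISO 3950) tooth codes
#'
#' FDI notation writes each permanent tooth as two digits: the quadrant
#' (1 = maxillary right, 2 = maxillary left, 3 = mandibular left,
#' 4 = mandibular right) followed by the position from the midline
#' (1 = central incisor ... 8 = third molar).
#'
#' @param codes character or integer vector of two-digit codes, e.g. `"31"`.
#' @return A tibble with one row per input code: `tooth_fdi`, `quadrant`,
#'   `position`, `arch` (`"maxillary"`/`"mandibular"`), `side`
#'   (`"right"`/`"left"`) and `tooth_name` (anatomical position name).
#' @export
#' @examples
#' parse_fdi(c("31", "48"))
parse_fdi <- function(codes) {
  txt <- as.character(codes)
  bad_form <- is.na(txt) | !grepl("^[0-9]{2}$", txt)
  if (any(bad_form)) {
    abort(paste0(
      "invalid FDI tooth code(s): ",
      paste(unique(ifelse(is.na(txt[bad_form]), "NA", txt[bad_form])), collapse = ", "),
      " (expected two digits, quadrant 1-4 then position 1-8)"
    ))
  }
  q <- as.integer(substr(txt, 1, 1))
  p <- as.integer(substr(txt, 2, 2))
  bad <- q < 1L | q > 4L | p < 1L | p > 8L
  if (any(bad)) {
    abort(paste0(
      "FDI tooth code(s) out of range: ", paste(unique(txt[bad]), collapse = ", "),
      " (quadrant must be 1-4, position 1-8)"
    ))
  }
  tibble(
    tooth_fdi = txt,
    quadrant = q,
    position = p,
    arch = ifelse(q <= 2L, "maxillary", "mandibular"),
    side = ifelse(q %in% c(1L, 4L), "right", "left"),
    tooth_name = POSITION_NAMES[p]
  )
}

POSITION_NAMES <- c(
  "central incisor", "lateral incisor", "canine", "first premolar",
  "second premolar", "first molar", "second molar", "third molar"
)

#' Contralateral tooth of an FDI code
#'
#' Mirrors a tooth across the midline within the same arch (11 <-> 21,
#' 36 <-> 46, ...). Used for bilateral fallback when one side of a pair is
#' unassessable.
#'
#' @param codes character vector of FDI codes.
#' @return character vector of mirrored codes.
#' @export
#' @examples
#' contralateral_fdi(c("31", "16"))
contralateral_fdi <- function(codes) {
  info <- parse_fdi(codes)
  mirror <- c(`1` = 2L, `2` = 1L, `3` = 4L, `4` = 3L)
  paste0(mirror[as.character(info$quadrant)], info$position)
}

#' Reference table of the permanent dentition in FDI notation
#'
#' A 32-row table mapping each FDI code to its anatomical description, for
#' readers more used to tooth names than codes.
#'
#' @return A tibble with `tooth_fdi`, `quadrant`, `position`, `arch`, `side`,
#'   `tooth_name`.
#' @export
fdi_reference <- function() {
  codes <- as.vector(outer(1:4, 1:8, function(q, p) paste0(q, p)))
  parse_fdi(sort(codes))
}
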