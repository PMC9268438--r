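# Monoisotopic atomic masses (Da) for the elements occurring in ginsenoside
# formulas, plus the electron mass used by the charged-adduct conventions.
ELEMENT_MASSES <- c(C = 12.0, H = 1.0078250319, O = 15.9949146221,
                    N = 14.0030740052, S = 31.97207069, P = 30.97376151)
ELECTRON_MASS <- 0.0005485799

#' Parse an elemental formula
#'
#' Accepts compact Hill-style formulas such as `"C42H72O14"`; element symbols
#' are one capital optionally followed by a lowercase letter, counts default
#' to 1, repeated symbols accumulate.
#'
#' @param s Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop_field("formula", "must be a nonempty string")
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(s)) {
    m <- regmatches(substr(s, pos, nchar(s)),
                    regexpr("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, nchar(s))))
    if (length(m) == 0 || !nzchar(m))
      stop(sprintf("malformed formula '%s' at position %d", s, pos), call. = FALSE)
    elt <- gsub("[0-9]", "", m)
    if (!elt %in% names(ELEMENT_MASSES))
      stop(sprintf("unsupported element '%s' in '%s' at position %d", elt, s, pos),
           call. = FALSE)
    num <- gsub("[^0-9]", "", m)
    k <- if (nzchar(num)) as.integer(num) else 1L
    counts[elt] <- (if (elt %in% names(counts)) counts[[elt]] else 0L) + k
    pos <- pos + nchar(m)
  }
  counts
}

#' Monoisotopic mass of an element count map
#'
#' @param counts Named integer vector as returned by [parse_formula()], or a
#'   formula string.
#' @return Mass in Da (0 for an empty map).
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (length(counts) == 0) return(0)
  unknown <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(unknown))
    stop(sprintf("no monoisotopic mass for element(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sum(counts * ELEMENT_MASSES[names(counts)])
}

#' Negative-mode adduct m/z
#'
#' Theoretical m/z of the two adducts ginsenosides form in negative mode:
#' the deprotonated ion `[M-H]-` and the formate adduct `[M+HCOO]-`. The
#' default convention accounts for the electron carried by the anion
#' (`[M-H]-` = M minus a proton); `electron = FALSE` switches to plain
#' neutral-fragment arithmetic (M minus a hydrogen atom, M plus neutral
#' HCOO), the spread between the two being ~0.5 mDa.
#'
#' @param M Neutral monoisotopic mass in Da (> 0).
#' @param ion_type `"[M-H]-"` or `"[M+HCOO]-"`.
#' @param electron Include the electron mass in the ion (default TRUE).
#' @return Ion m/z in Da. A non-positive result (degenerate `M`) warns.
#' @export
adduct_mz <- function(M, ion_type, electron = TRUE) {
  if (!is.numeric(M) || any(M <= 0)) stop_field("M", "must be > 0")
  h <- ELEMENT_MASSES[["H"]]
  hcoo <- ELEMENT_MASSES[["H"]] + ELEMENT_MASSES[["C"]] + 2 * ELEMENT_MASSES[["O"]]
  e <- if (electron) ELECTRON_MASS else 0
  mz <- switch(ion_type,
    "[M-H]-" = M - h + e,
    "[M+HCOO]-" = M + hcoo + e,
    stop(sprintf("unknown ion type '%s'", ion_type), call. = FALSE))
  if (any(mz < 1e-6)) warning("degenerate adduct: m/z at or below zero")
  mz
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values in Da; `theoretical` > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop_field("theoretical", "must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

# Diagnostic aglycone fragments (Da): protopanaxatriol, protopanaxadiol and
# oleanolic acid nuclei, the stable parent cores of the three ginsenoside
# families.
AGLYCONE_FRAGMENTS <- c(PPT = 475.38, PPD = 459.38, OA = 455.35)

#' Classify a ginsenoside aglycone family from MS/MS fragments
#'
#' PPT if any fragment lies within `tol` of m/z 475.38, PPD for 459.38, OA
#' for 455.35 (precedence PPT > PPD > OA when several match), otherwise
#' `"unknown"`.
#'
#' @param fragments Numeric vector of fragment m/z values (may be empty).
#' @param tol Match window in Da (default 0.05, the Q-TOF accuracy scale).
#' @return One of `"PPT"`, `"PPD"`, `"OA"`, `"unknown"`.
#' @export
classify_aglycone <- function(fragments, tol = 0.05) {
  if (length(fragments) == 0) return("unknown")
  for (cls in names(AGLYCONE_FRAGMENTS))
    if (any(abs(fragments - AGLYCONE_FRAGMENTS[[cls]]) <= tol)) return(cls)
  "unknown"
}

#' Load the packaged ginsenoside reference table
#'
#' Reads the 69-record reference table of characteristic ginsenosides
#' (retention time, formula, measured adduct m/z, ion type, reported ppm
#' error, MS/MS fragment ions) and augments it with the parsed neutral
#' monoisotopic mass, the theoretical adduct m/z, the recomputed ppm error of
#' the tabulated m/z, and the aglycone family inferred from the fragments.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @param electron Adduct-mass convention passed to [adduct_mz()].
#' @return `data.frame` of class `ginsenoside_db` with one row per record and
#'   a `fragment_ions` list column.
#' @export
load_ginsenoside_db <- function(path = system.file("extdata",
                                                   "ginsenosides_table1.csv",
                                                   package = "ginsengms"),
                                electron = TRUE) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("no", "rt_min", "name", "formula", "mass_ion_mz", "ion_type",
            "error_ppm", "fragment_ions")
  if (!all(need %in% names(db)))
    stop_field("db", paste("missing columns:",
                           paste(setdiff(need, names(db)), collapse = ", ")))
  if (!all(db$ion_type %in% c("[M-H]-", "[M+HCOO]-")))
    stop_field("ion_type", "must be [M-H]- or [M+HCOO]-")
  db$fragment_ions <- lapply(strsplit(db$fragment_ions, ";", fixed = TRUE),
                             function(x) as.numeric(x[nzchar(x)]))
  db$neutral_mass <- vapply(db$formula, monoisotopic_mass, numeric(1))
  db$theoretical_mz <- mapply(adduct_mz, db$neutral_mass, db$ion_type,
                              MoreArgs = list(electron = electron))
  db$recomputed_ppm <- ppm_error(db$mass_ion_mz, db$theoretical_mz)
  db$aglycone_class <- vapply(db$fragment_ions, classify_aglycone, character(1))
  class(db) <- c("ginsenoside_db", class(db))
  db
}

#' Annotate aligned features against a ginsenoside reference table
#'
#' Matches every feature of a [feature_table()] to all reference records
#' whose theoretical adduct m/z lies within `mz_tol_ppm` and whose retention
#' time lies within `rt_tol`. A feature can collect zero, one, or several
#' hits (isomers share a formula); hits are sorted by absolute ppm error.
#'
#' @param ft A [feature_table()].
#' @param db A [load_ginsenoside_db()] table (nonempty).
#' @param mz_tol_ppm Mass tolerance in ppm (> 0).
#' @param rt_tol Retention-time tolerance in minutes (> 0).
#' @return `data.frame` with columns `feature`, `record_no`, `name`,
#'   `observed_mz`, `theoretical_mz`, `ppm_error`, `rt_delta`,
#'   `aglycone_class`.
#' @export
annotate_features <- function(ft, db, mz_tol_ppm = 15, rt_tol = 0.5) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.data.frame(db) || nrow(db) == 0)
    stop_field("db", "reference table is empty")
  if (!is.numeric(mz_tol_ppm) || mz_tol_ppm <= 0) stop_field("mz_tol_ppm", "must be > 0")
  if (!is.numeric(rt_tol) || rt_tol <= 0) stop_field("rt_tol", "must be > 0")

  meta <- ft$feature_meta
  hits <- lapply(seq_len(nrow(meta)), function(i) {
    pe <- ppm_error(meta$mz[i], db$theoretical_mz)
    dt <- meta$rt[i] - db$rt_min
    ok <- abs(pe) <= mz_tol_ppm & abs(dt) <= rt_tol
    if (!any(ok)) return(NULL)
    data.frame(feature = meta$feature[i], record_no = db$no[ok],
               name = db$name[ok], observed_mz = meta$mz[i],
               theoretical_mz = db$theoretical_mz[ok], ppm_error = pe[ok],
               rt_delta = dt[ok], aglycone_class = db$aglycone_class[ok])
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(feature = character(0), record_no = integer(0),
                      name = character(0), observed_mz = numeric(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      rt_delta = numeric(0), aglycone_class = character(0))
  out[order(abs(out$ppm_error)), , drop = FALSE]
}
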