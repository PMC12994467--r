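# Fixed linear transforms between the orthogonal-lead VCG and the 8
# independent ECG leads (I, II, V1-V6). The four derived limb leads are never
# stored as matrix rows; they follow algebraically from I and II
# (Einthoven/Goldberger identities).

dower_matrix_values <- function() {
  # E. Dower's classic lead-vector matrix (VCG -> 8 independent leads).
  m <- rbind(
    I  = c(0.632, -0.235,  0.059),
    II = c(0.235,  1.066, -0.132),
    V1 = c(-0.515, 0.157, -0.917),
    V2 = c(0.044,  0.164, -1.387),
    V3 = c(0.882,  0.098, -1.277),
    V4 = c(1.213,  0.127, -0.601),
    V5 = c(1.125,  0.127, -0.086),
    V6 = c(0.831,  0.076,  0.230)
  )
  colnames(m) <- c("X", "Y", "Z")
  m
}

uijen_standin_values <- function() {
  # SYNTHETIC STAND-IN. The Uijen regression coefficients for VCG -> ECG
  # reconstruction are not packaged here; this slot is filled with the
  # minimum-norm reconstruction matrix derived as the Moore-Penrose
  # pseudoinverse of the Kors ECG -> VCG regression matrix, frozen to four
  # decimals. It plays the structural role of a second, regression-style
  # transform distinct from Dower's; replace via `transform_matrix(values=)`
  # when the genuine coefficients are available.
  m <- rbind(
    I  = c( 0.9534, -0.1149, -0.3458),
    II = c(-0.0455,  0.9889, -0.0683),
    V1 = c( 0.3991, -0.2007, -1.3443),
    V2 = c( 0.2682, -0.0822, -0.3359),
    V3 = c( 0.2468, -0.1595, -0.5486),
    V4 = c( 0.7776, -0.1117, -0.9779),
    V5 = c( 0.4349, -0.3044, -0.6529),
    V6 = c( 1.0009,  0.2281,  0.2578)
  )
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' VCG-to-ECG transform matrices
#'
#' Returns a named transform mapping the orthogonal leads (X, Y, Z) to the 8
#' independent ECG leads. `"dower"` carries Dower's published lead-vector
#' coefficients. `"uijen"` is a regression-style alternative; because the
#' original Uijen coefficients are not redistributed here, its default values
#' are a synthetic stand-in (pseudoinverse of the Kors ECG-to-VCG regression
#' matrix) and are flagged as such in the object's `citation` field.
#'
#' @param name `"dower"` or `"uijen"`, or any label when `values` is given.
#' @param values Optional replacement 8 x 3 matrix (rows I, II, V1-V6;
#'   columns X, Y, Z) overriding the built-in coefficients.
#' @return A `transform_matrix` object: list with `name`, `rows` (8 x 3
#'   matrix), `citation`.
#' @export
transform_matrix <- function(name = c("dower", "uijen"), values = NULL) {
  if (is.null(values)) {
    name <- match.arg(name)
    values <- switch(name,
                     dower = dower_matrix_values(),
                     uijen = uijen_standin_values())
    citation <- switch(name,
      dower = "Dower GE (1968), lead-vector synthesis matrix (published values).",
      uijen = paste("SYNTHETIC STAND-IN for the Uijen regression matrix:",
                    "Moore-Penrose pseudoinverse of the Kors (1990)",
                    "ECG-to-VCG regression matrix."))
  } else {
    name <- as.character(name)[1]
    citation <- "user-supplied"
  }
  values <- as.matrix(values)
  if (!all(c("I", "II", precordial_leads()) %in% rownames(values)) ||
      ncol(values) != 3)
    abort_pronecg("FormatError",
                  "transform matrix needs rows I, II, V1-V6 and 3 columns")
  values <- values[c("I", "II", precordial_leads()), ]
  colnames(values) <- c("X", "Y", "Z")
  structure(list(name = name, rows = values, citation = citation),
            class = "transform_matrix")
}

#' @export
print.transform_matrix <- function(x, ...) {
  cat(sprintf("<transform_matrix> %s\n", x$name))
  print(round(x$rows, 4))
  cat(x$citation, "\n")
  invisible(x)
}

# Expand 8 independent rows to all 12 leads using the limb identities:
# III = II - I, aVR = -(I+II)/2, aVL = I - II/2, aVF = II - I/2.
expand_to_12 <- function(rows8) {
  r <- rows8
  full <- rbind(
    I   = r["I", ],
    II  = r["II", ],
    III = r["II", ] - r["I", ],
    aVR = -(r["I", ] + r["II", ]) / 2,
    aVL = r["I", ] - r["II", ] / 2,
    aVF = r["II", ] - r["I", ] / 2,
    r[precordial_leads(), ]
  )
  rownames(full) <- ecg_leads()
  full
}

#' Project a VCG onto the 12 standard leads
#'
#' Applies a VCG-to-ECG transform: the 8 independent leads are linear
#' projections of (X, Y, Z); the remaining limb leads follow from the
#' Einthoven/Goldberger identities, so `III = II - I`, `aVR = -(I + II)/2`,
#' `aVL = I - II/2`, `aVF = II - I/2` hold exactly on every output.
#'
#' @param vcg A [vcg_record()].
#' @param matrix A [transform_matrix()].
#' @return An [ecg_record()] tagged `posture = "supine"`.
#' @export
vcg_to_ecg <- function(vcg, matrix = transform_matrix("dower")) {
  stopifnot(inherits(vcg, "vcg_record"), inherits(matrix, "transform_matrix"))
  full <- expand_to_12(matrix$rows)
  signals <- vcg$xyz %*% t(full)
  ecg_record(signals, fs = vcg$fs, posture = "supine",
             subject_id = vcg$subject_id)
}
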