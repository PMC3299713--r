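#' Phenotype codes
#'
#' The five cell phenotypes tracked by the model, in canonical order. The
#' integer code of a phenotype is its position in this vector minus one (the
#' coding used by the C++ engine).
#'
#' @format Character vector of length 5.
#' @export
PHENOTYPES <- c("HESC", "MESENDODERM", "VISCERAL_ENDODERM",
                "DEFINITIVE_ENDODERM", "MESODERM")

PROLIF_SCOPES <- c("ALL", "ENDODERM_AND_UNCOMMITTED", "UNCOMMITTED_ONLY")
SCOPE_CODES <- c(ALL = "A", ENDODERM_AND_UNCOMMITTED = "EU",
                 UNCOMMITTED_ONLY = "U")

#' Candidate differentiation mechanism
#'
#' A mechanism hypothesis is the combination of three attributes: whether an
#' intermediate mesendoderm germ layer exists (two-stage differentiation),
#' whether mesoderm expresses the surface marker CXCR4, and which phenotypes
#' are allowed to proliferate. The 2 x 2 x 3 combinations give the twelve
#' candidate mechanisms. Named mechanisms from the mechanism-selection
#' analysis: Mechanism A = `"ME+/CX+/EU"`, Mechanism B = `"ME+/CX-/EU"`,
#' Mechanism C = `"ME+/CX+/A"`.
#'
#' @param include_mesendoderm Logical. With mesendoderm, stage-1 hESC commit
#'   to mesendoderm or visceral endoderm, and stage-2 mesendoderm commits to
#'   definitive endoderm or mesoderm. Without it, hESC commit directly to
#'   definitive endoderm, visceral endoderm or mesoderm in a single stage.
#' @param cxcr4_in_mesoderm Logical; whether mesoderm counts as CXCR4+.
#' @param proliferation_scope One of `"ALL"`, `"ENDODERM_AND_UNCOMMITTED"`,
#'   `"UNCOMMITTED_ONLY"` (abbreviations `"A"`, `"EU"`, `"U"` accepted).
#' @param id Alternatively, a canonical id string such as `"ME+/CX-/EU"`; if
#'   supplied it overrides the three attribute arguments.
#'
#' @return An object of class `"mechanism"` with fields
#'   `include_mesendoderm`, `cxcr4_in_mesoderm`, `proliferation_scope`, `id`.
#' @examples
#' mechanism(id = "ME+/CX-/EU")          # Mechanism B
#' mechanism(TRUE, TRUE, "ALL")          # Mechanism C
#' @export
mechanism <- function(include_mesendoderm = TRUE, cxcr4_in_mesoderm = FALSE,
                      proliferation_scope = "ENDODERM_AND_UNCOMMITTED",
                      id = NULL) {
  if (!is.null(id)) {
    parts <- strsplit(id, "/", fixed = TRUE)[[1]]
    if (length(parts) != 3L || !parts[1] %in% c("ME+", "ME-") ||
        !parts[2] %in% c("CX+", "CX-") || !parts[3] %in% SCOPE_CODES)
      stop("malformed mechanism id: '", id,
           "' (expected e.g. \"ME+/CX-/EU\")")
    include_mesendoderm <- parts[1] == "ME+"
    cxcr4_in_mesoderm <- parts[2] == "CX+"
    proliferation_scope <- names(SCOPE_CODES)[match(parts[3], SCOPE_CODES)]
  }
  if (proliferation_scope %in% SCOPE_CODES)
    proliferation_scope <-
      names(SCOPE_CODES)[match(proliferation_scope, SCOPE_CODES)]
  proliferation_scope <- match.arg(proliferation_scope, PROLIF_SCOPES)
  stopifnot(is.logical(include_mesendoderm), length(include_mesendoderm) == 1,
            is.logical(cxcr4_in_mesoderm), length(cxcr4_in_mesoderm) == 1)
  structure(list(
    include_mesendoderm = include_mesendoderm,
    cxcr4_in_mesoderm = cxcr4_in_mesoderm,
    proliferation_scope = proliferation_scope,
    id = paste0(if (include_mesendoderm) "ME+" else "ME-", "/",
                if (cxcr4_in_mesoderm) "CX+" else "CX-", "/",
                SCOPE_CODES[[proliferation_scope]])
  ), class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  cat("Mechanism ", x$id, ": ",
      if (x$include_mesendoderm) "mesendoderm intermediate (two-stage)"
      else "direct single-stage differentiation",
      ", CXCR4 ", if (x$cxcr4_in_mesoderm) "present" else "absent",
      " in mesoderm, proliferation: ", x$proliferation_scope, "\n", sep = "")
  invisible(x)
}

#' Enumerate the twelve candidate mechanisms
#'
#' All 2 x 2 x 3 combinations of mesendoderm inclusion, CXCR4 expression in
#' mesoderm, and proliferation scope, in a stable canonical order.
#'
#' @return A list of 12 [mechanism()] objects, named by their ids.
#' @examples
#' length(enumerate_mechanisms())
#' @export
enumerate_mechanisms <- function() {
  grid <- expand.grid(scope = PROLIF_SCOPES, cx = c(TRUE, FALSE),
                      me = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    mechanism(grid$me[i], grid$cx[i], grid$scope[i]))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Is a phenotype allowed to proliferate under a mechanism?
#'
#' Proliferation scope `"UNCOMMITTED_ONLY"` allows division of hESC and
#' mesendoderm; `"ENDODERM_AND_UNCOMMITTED"` additionally allows definitive
#' endoderm (visceral endoderm is excluded: only the definitive branch is
#' selectively expanded); `"ALL"` allows every phenotype. A cell must also be
#' proliferation-competent (affinity below `a_min`) and within its
#' proliferation window for an actual division to occur.
#'
#' @param phenotype Character vector of phenotype names (see [PHENOTYPES]).
#' @param mech A [mechanism()].
#' @return Logical vector.
#' @examples
#' proliferation_allowed("MESODERM", mechanism(id = "ME+/CX+/A"))
#' proliferation_allowed("MESODERM", mechanism(id = "ME+/CX-/EU"))
#' @export
proliferation_allowed <- function(phenotype, mech) {
  stopifnot(inherits(mech, "mechanism"))
  phenotype <- match.arg(phenotype, PHENOTYPES, several.ok = TRUE)
  allowed <- switch(mech$proliferation_scope,
    ALL = PHENOTYPES,
    ENDODERM_AND_UNCOMMITTED = c("HESC", "MESENDODERM",
                                 "DEFINITIVE_ENDODERM"),
    UNCOMMITTED_ONLY = c("HESC", "MESENDODERM"))
  phenotype %in% allowed
}

#' Marker-positive fractions from phenotype counts
#'
#' Maps per-phenotype live counts to the two experimentally observable marker
#' fractions. Sox17 marks visceral and definitive endoderm. CXCR4 marks
#' definitive endoderm and mesendoderm, plus mesoderm if and only if the
#' mechanism expresses CXCR4 in mesoderm. Marker positivity is
#' commitment-gated: only committed germ-layer cells count.
#'
#' @param counts Named numeric vector (or matrix with named columns) of live
#'   cell counts per phenotype; names must cover [PHENOTYPES].
#' @param mech A [mechanism()].
#' @return A list with numeric elements `frac_sox17` and `frac_cxcr4` (vectors
#'   if `counts` is a matrix).
#' @examples
#' cnt <- c(HESC = 1, MESENDODERM = 0, VISCERAL_ENDODERM = 0,
#'          DEFINITIVE_ENDODERM = 2, MESODERM = 1)
#' marker_fractions(cnt, mechanism(id = "ME+/CX+/EU"))
#' @export
marker_fractions <- function(counts, mech) {
  stopifnot(inherits(mech, "mechanism"))
  if (is.matrix(counts)) {
    stopifnot(all(PHENOTYPES %in% colnames(counts)))
    get <- function(ph) counts[, ph]
  } else {
    stopifnot(all(PHENOTYPES %in% names(counts)))
    get <- function(ph) counts[[ph]]
  }
  live <- get("HESC") + get("MESENDODERM") + get("VISCERAL_ENDODERM") +
    get("DEFINITIVE_ENDODERM") + get("MESODERM")
  if (any(live <= 0))
    stop("marker fractions undefined: live total is zero")
  cx <- get("DEFINITIVE_ENDODERM") + get("MESENDODERM") +
    if (mech$cxcr4_in_mesoderm) get("MESODERM") else 0
  list(frac_sox17 = unname((get("VISCERAL_ENDODERM") +
                              get("DEFINITIVE_ENDODERM")) / live),
       frac_cxcr4 = unname(cx / live))
}
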