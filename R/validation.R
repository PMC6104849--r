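#' Default photo-tag to land-cover-code mapping
#'
#' Reads the editable mapping shipped with the package
#' (`extdata/class_mapping.csv`): one row per (tag, code) pair, NLCD-style
#' integer codes. "beach" maps to the barren class (31), which includes
#' sand; "water" to open water (11); "urban" to the four developed classes.
#'
#' @param path Optional path to an alternative mapping CSV with columns
#'   `tag` and `code`.
#' @return A data.frame with character `tag` and integer `code`.
#' @export
default_class_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "class_mapping.csv", package = "cesviews",
                        mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tag", "code") %in% names(m)))
  m$code <- as.integer(m$code)
  m
}

map_codes <- function(mapping, tag) {
  codes <- mapping$code[mapping$tag == tag]
  if (length(codes) == 0)
    stop("unmapped tag '", tag, "'; known tags: ",
         paste(sort(unique(mapping$tag)), collapse = ", "))
  codes
}

#' Is a land-cover class present in a viewshed?
#'
#' @param vs A `ces_viewshed`.
#' @param landcover Aligned categorical [ces_raster()].
#' @param class_tag Tag to test (resolved through `mapping`).
#' @param min_fraction Minimum visible fraction required. The default 0
#'   means "any visible cell of the class" (i.e. fraction strictly greater
#'   than zero); a positive threshold is compared inclusively.
#' @param mapping Tag-to-code mapping, see [default_class_mapping()].
#' @return Logical.
#' @export
viewshed_presence <- function(vs, landcover, class_tag, min_fraction = 0,
                              mapping = default_class_mapping()) {
  codes <- map_codes(mapping, class_tag)
  comp <- composition(vs, landcover)
  frac <- sum(comp[names(comp) %in% as.character(codes)])
  if (min_fraction <= 0) frac > 0 else frac >= min_fraction
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary raters:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d) / n` and chance agreement `p_e` from the marginal
#' products. In the degenerate case `p_e = 1`, perfect observed agreement
#' returns 1; imperfect agreement is an error.
#'
#' @param a,b,c,d Counts: `a` both raters present, `b` rater-1 only,
#'   `c` rater-2 only, `d` both absent. Alternatively pass a 2x2 matrix
#'   as `a` (rows = rater 1, columns = rater 2, "present" first).
#' @return Kappa (dimensionless, `<= 1`).
#' @examples
#' kappa_2x2(40, 10, 10, 40)  # p_o = 0.8, p_e = 0.5 -> 0.6
#' @export
kappa_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty agreement table")
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("degenerate table: chance agreement is 1 but observed agreement is not")
  }
  (p_o - p_e) / (1 - p_e)
}

photo_tag_list <- function(labels) {
  if (is.list(labels)) return(lapply(labels, as.character))
  lapply(strsplit(ifelse(is.na(labels), "", labels), ";"),
         function(v) trimws(v[nzchar(trimws(v))]))
}

#' Relevance summary of a labelled photo sample
#'
#' The reporting stage for the manually classified subsample: how many
#' photos depict content relevant to cultural-ecosystem-service use, and
#' the complementary fraction of non-relevant material (advertisements,
#' scans, and the like).
#'
#' @param photos A data.frame with a logical column `relevant`.
#' @return A list: `n_total`, `n_relevant`, `n_nonrelevant`, `pct_relevant`,
#'   `pct_nonrelevant` (percentages of the total).
#' @export
relevance_summary <- function(photos) {
  stopifnot(is.data.frame(photos), "relevant" %in% names(photos))
  rel <- as.logical(photos$relevant)
  n <- length(rel)
  if (n == 0) stop("empty photo table")
  nr <- sum(rel)
  list(n_total = n, n_relevant = nr, n_nonrelevant = n - nr,
       pct_relevant = 100 * nr / n, pct_nonrelevant = 100 * (n - nr) / n)
}

#' Per-class agreement between photo labels and viewshed-visible land cover
#'
#' For each land-class tag in the mapping, cross-tabulates presence in the
#' photo's labels against presence in the photo's viewshed and reports
#' percent agreement and Cohen's kappa. Only relevant photos carrying at
#' least one mapped land-class tag enter the comparison.
#'
#' @param photos Data.frame with columns `id`, `relevant`, and `labels`
#'   (character `";"`-separated tags, or a list column of character vectors).
#' @param viewsheds Named list of `ces_viewshed` keyed by photo id, or a
#'   function `id -> ces_viewshed`.
#' @param landcover Aligned categorical [ces_raster()].
#' @param mapping Tag-to-code mapping, see [default_class_mapping()].
#' @param min_fraction Passed to [viewshed_presence()].
#' @return A data.frame, one row per tag: counts `a`, `b`, `c`, `d`, `n`,
#'   `percent_agreement`, `kappa`.
#' @export
agreement_report <- function(photos, viewsheds, landcover,
                             mapping = default_class_mapping(),
                             min_fraction = 0) {
  tags <- sort(unique(mapping$tag))
  labs <- photo_tag_list(photos$labels)
  land_tags <- lapply(labs, function(v) intersect(v, tags))
  keep <- as.logical(photos$relevant) & lengths(land_tags) > 0
  ids <- as.character(photos$id)[keep]
  land_tags <- land_tags[keep]
  if (length(ids) == 0) stop("no relevant photos with mapped land-class tags")
  get_vs <- if (is.function(viewsheds)) viewsheds else function(id) {
    vs <- viewsheds[[id]]
    if (is.null(vs)) stop("no viewshed computed for photo '", id, "'")
    vs
  }
  vs_pres <- matrix(FALSE, length(ids), length(tags),
                    dimnames = list(ids, tags))
  for (i in seq_along(ids)) {
    vs <- get_vs(ids[i])
    comp <- composition(vs, landcover)
    for (tg in tags) {
      frac <- sum(comp[names(comp) %in% as.character(map_codes(mapping, tg))])
      vs_pres[i, tg] <- if (min_fraction <= 0) frac > 0 else frac >= min_fraction
    }
  }
  ph_pres <- vapply(tags, function(tg)
    vapply(land_tags, function(v) tg %in% v, logical(1)), logical(length(ids)))
  ph_pres <- matrix(ph_pres, nrow = length(ids))
  out <- do.call(rbind, lapply(seq_along(tags), function(j) {
    p <- ph_pres[, j]; v <- vs_pres[, j]
    a <- sum(p & v); b <- sum(p & !v); cc <- sum(!p & v); d <- sum(!p & !v)
    n <- a + b + cc + d
    data.frame(class_tag = tags[j], a = a, b = b, c = cc, d = d, n = n,
               percent_agreement = 100 * (a + d) / n,
               kappa = kappa_2x2(a, b, cc, d))
  }))
  rownames(out) <- NULL
  out
}
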