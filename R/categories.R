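#' Build a comparison table for the category engine
#'
#' Normalizes a named list of per-comparison statistics into the structure
#' the classification operations consume. Every element must share one
#' feature universe. Methylation fits contribute their delta-beta as the
#' effect; expression fits contribute the model log2 fold change. A
#' comparison passes for a feature iff \code{|effect| > effect_min} and
#' \code{p < p_max} (both strict); callers may instead supply their own
#' \code{pass} column (e.g. full DEG criteria including the RPKM gate and
#' sign-agreement filter), which is taken as-is.
#'
#' @param stats named list (names = comparison ids, e.g.
#'   \code{"T3_vs_RPMI@24h"}) of \code{dm_fit} / \code{de_fit} data frames,
#'   or plain data frames with \code{feature_id}, \code{effect}, \code{p}
#'   and optionally \code{pass}.
#' @param effect_min minimum absolute effect applied where no \code{pass}
#'   column is given (default 0.05, the delta-beta cut-off).
#' @param p_max maximum p-value (default 0.05).
#' @return object of class \code{comparison_table}: list of normalized data
#'   frames (feature_id, effect, p, pass) over a common feature universe.
#' @export
comparison_table <- function(stats, effect_min = 0.05, p_max = 0.05) {
  if (is.null(names(stats)) || any(names(stats) == "")) {
    stop("'stats' must be a named list keyed by comparison id")
  }
  norm <- lapply(names(stats), function(id) {
    x <- stats[[id]]
    # delta-beta / log2FC are the threshold-bearing effect sizes; a plain
    # "effect" column (e.g. the M-scale model coefficient) is only used
    # when neither is present
    eff <- if ("delta_beta" %in% names(x)) x$delta_beta
      else if ("log2fc" %in% names(x)) x$log2fc
      else if ("effect" %in% names(x)) x$effect
      else stop("comparison '", id, "' has no effect column")
    p <- x$p
    pass <- if ("pass" %in% names(x)) {
      x$pass
    } else {
      !is.na(eff) & !is.na(p) & abs(eff) > effect_min & p < p_max
    }
    pass[is.na(pass)] <- FALSE
    data.frame(feature_id = x$feature_id, effect = eff, p = p, pass = pass,
               stringsAsFactors = FALSE)
  })
  names(norm) <- names(stats)
  universe <- sort(norm[[1]]$feature_id)
  for (id in names(norm)) {
    if (!identical(sort(norm[[id]]$feature_id), universe)) {
      stop("comparison '", id, "' does not share the common feature universe")
    }
    norm[[id]] <- norm[[id]][match(universe, norm[[id]]$feature_id), ]
    rownames(norm[[id]]) <- NULL
  }
  structure(norm, class = "comparison_table",
            thresholds = c(effect = effect_min, p = p_max))
}

get_comparison <- function(tbl, id) {
  if (!id %in% names(tbl)) {
    stop("comparison table is missing comparison '", id,
         "'; configure the comparison schedule to include it", call. = FALSE)
  }
  tbl[[id]]
}

new_category_set <- function(feature_id, category, direction, provenance) {
  out <- data.frame(feature_id = feature_id,
                    category = rep(category, length.out = length(feature_id)),
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("category_set", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' Classify treatment-induced features
#'
#' A feature belongs to the induced set iff it passes its thresholds against
#' EVERY reference arm with the SAME effect sign; the shared sign becomes
#' its direction (GAIN/LOSS). With references \code{"ZERO_H"} this defines
#' the differentiation-associated set; with \code{c("RPMI", "ZERO_H")} the
#' T3-specific set; with \code{c("T3", "RPMI", "ZERO_H")} the co-stimulation
#' specific set.
#'
#' @param tbl a [comparison_table()].
#' @param target target arm.
#' @param references character vector of reference arms.
#' @param timepoint_h timepoint of the comparisons, default 24.
#' @param category label stored on the result.
#' @return a \code{category_set} data frame (feature_id, category,
#'   direction) with a long-format \code{provenance} attribute listing the
#'   contributing comparisons with their effects and p-values.
#' @export
classify_induced <- function(tbl, target, references, timepoint_h = 24,
                             category = paste0(target, "_INDUCED")) {
  ids <- sprintf("%s_vs_%s@%sh", target, references, timepoint_h)
  comps <- lapply(ids, get_comparison, tbl = tbl)
  pass <- Reduce(`&`, lapply(comps, function(x) x$pass))
  signs <- vapply(comps, function(x) sign(x$effect), numeric(nrow(comps[[1]])))
  if (is.null(dim(signs))) signs <- matrix(signs, nrow = 1)
  same_sign <- apply(signs, 1, function(s) all(s == s[1]) && s[1] != 0)
  keep <- which(pass & same_sign)
  fid <- comps[[1]]$feature_id[keep]
  direction <- ifelse(signs[keep, 1] > 0, "GAIN", "LOSS")
  prov <- do.call(rbind, lapply(seq_along(ids), function(k) {
    data.frame(feature_id = fid, comparison_id = rep(ids[k], length(keep)),
               effect = comps[[k]]$effect[keep], p = comps[[k]]$p[keep],
               stringsAsFactors = FALSE)
  }))
  new_category_set(fid, category, direction,
                   prov %||% data.frame(feature_id = character(),
                                        comparison_id = character(),
                                        effect = numeric(), p = numeric()))
}

#' Classify the LPS-induced set (union of two routes)
#'
#' LPS-induced features are those induced along either route: LPS versus
#' \{RPMI, 0 h\}, or T3+LPS versus \{T3, 0 h\}. The union is deduplicated;
#' each feature records which route(s) fired. Features whose two routes
#' disagree in direction are dropped with a message (ambiguous direction).
#'
#' @param tbl a [comparison_table()].
#' @param timepoint_h timepoint, default 24.
#' @return a \code{category_set} with a \code{route} column in the
#'   provenance attribute and a \code{routes} column (\code{"LPS"},
#'   \code{"T3_LPS"} or \code{"LPS+T3_LPS"}).
#' @export
classify_lps_induced <- function(tbl, timepoint_h = 24) {
  a <- classify_induced(tbl, "LPS", c("RPMI", "ZERO_H"), timepoint_h,
                        category = "LPS_INDUCED")
  b <- classify_induced(tbl, "T3_LPS", c("T3", "ZERO_H"), timepoint_h,
                        category = "LPS_INDUCED")
  dir_a <- setNames(a$direction, a$feature_id)
  dir_b <- setNames(b$direction, b$feature_id)
  both <- intersect(a$feature_id, b$feature_id)
  conflict <- both[dir_a[both] != dir_b[both]]
  if (length(conflict)) {
    message("classify_lps_induced: dropping ", length(conflict),
            " feature(s) with conflicting direction between routes")
  }
  ids <- setdiff(union(a$feature_id, b$feature_id), conflict)
  ids <- sort(ids)
  direction <- ifelse(ids %in% a$feature_id, dir_a[ids], dir_b[ids])
  routes <- ifelse(ids %in% both, "LPS+T3_LPS",
                   ifelse(ids %in% a$feature_id, "LPS", "T3_LPS"))
  prov_a <- attr(a, "provenance")
  prov_a$route <- "LPS"
  prov_b <- attr(b, "provenance")
  prov_b$route <- "T3_LPS"
  prov <- rbind(prov_a, prov_b)
  prov <- prov[prov$feature_id %in% ids, , drop = FALSE]
  out <- new_category_set(ids, "LPS_INDUCED", unname(direction), prov)
  out$routes <- routes
  out
}

#' Filter an induced set down to the attenuated subset
#'
#' A feature of the base (induced) set is attenuated iff the modifier
#' comparison (treatment-plus-modifier arm vs base arm, e.g. T3 vs RPMI or
#' T3+LPS vs LPS) passes its thresholds AND its effect sign is OPPOSITE to
#' the base direction: a gain of the base effect must be met by a
#' significant loss in the modifier comparison, and vice versa.
#'
#' @param base a \code{category_set} of induced features.
#' @param modifier_id comparison id of the modifier contrast.
#' @param tbl a [comparison_table()].
#' @param category label for the result.
#' @return \code{category_set} of the attenuated subset (directions are the
#'   base directions).
#' @export
classify_attenuated <- function(base, modifier_id, tbl,
                                category = paste0(base$category[1], "_ATTENUATED")) {
  mod <- get_comparison(tbl, modifier_id)
  if (nrow(base) == 0) {
    return(new_category_set(character(), character(), character(),
                            data.frame(feature_id = character(),
                                       comparison_id = character(),
                                       effect = numeric(), p = numeric())))
  }
  idx <- match(base$feature_id, mod$feature_id)
  base_sign <- ifelse(base$direction == "GAIN", 1, -1)
  ok <- mod$pass[idx] & sign(mod$effect[idx]) == -base_sign
  keep <- which(ok)
  prov <- rbind(
    attr(base, "provenance")[
      attr(base, "provenance")$feature_id %in% base$feature_id[keep],
      c("feature_id", "comparison_id", "effect", "p"), drop = FALSE],
    data.frame(feature_id = base$feature_id[keep],
               comparison_id = rep(modifier_id, length(keep)),
               effect = mod$effect[idx][keep], p = mod$p[idx][keep],
               stringsAsFactors = FALSE)
  )
  new_category_set(base$feature_id[keep], category, base$direction[keep], prov)
}

#' Filter a treatment-specific set down to the unique subset
#'
#' A feature of the specific set (e.g. T3+LPS vs T3, RPMI and 0 h) is
#' "unique" iff the versus comparison (e.g. T3+LPS vs LPS) also passes its
#' thresholds with the SAME sign as the specific direction, i.e. the feature
#' differs from every other treatment group including the single agonist.
#'
#' @param specific a \code{category_set}.
#' @param versus_id comparison id of the remaining contrast.
#' @param tbl a [comparison_table()].
#' @param category label for the result.
#' @return \code{category_set} of the unique subset.
#' @export
classify_unique <- function(specific, versus_id, tbl,
                            category = "T3LPS_UNIQUE") {
  ver <- get_comparison(tbl, versus_id)
  if (nrow(specific) == 0) {
    return(new_category_set(character(), character(), character(),
                            data.frame(feature_id = character(),
                                       comparison_id = character(),
                                       effect = numeric(), p = numeric())))
  }
  idx <- match(specific$feature_id, ver$feature_id)
  spec_sign <- ifelse(specific$direction == "GAIN", 1, -1)
  ok <- ver$pass[idx] & sign(ver$effect[idx]) == spec_sign
  keep <- which(ok)
  prov <- rbind(
    attr(specific, "provenance")[
      attr(specific, "provenance")$feature_id %in% specific$feature_id[keep],
      c("feature_id", "comparison_id", "effect", "p"), drop = FALSE],
    data.frame(feature_id = specific$feature_id[keep],
               comparison_id = rep(versus_id, length(keep)),
               effect = ver$effect[idx][keep], p = ver$p[idx][keep],
               stringsAsFactors = FALSE)
  )
  new_category_set(specific$feature_id[keep], category,
                   specific$direction[keep], prov)
}

#' Partition genes into response tertiles
#'
#' Ranks genes in descending order of the modifier-to-base ratio of group
#' mean expression (e.g. mean RPKM T3+LPS / mean RPKM LPS) and splits them
#' into three groups: top third ENHANCED, middle NO_EFFECT, bottom third
#' ABROGATED. Sizes differ by at most one, extras are assigned top-first;
#' ties in the ratio are broken by gene id (lexicographic).
#'
#' @param ratios named numeric vector (names = gene ids) of mean-expression
#'   ratios, or a data frame with \code{feature_id} and \code{ratio}.
#' @return data frame of class \code{tertile_partition}: \code{feature_id},
#'   \code{ratio}, \code{rank}, \code{tertile}.
#' @export
tertile_partition <- function(ratios) {
  if (is.data.frame(ratios)) {
    ratios <- setNames(ratios$ratio, ratios$feature_id)
  }
  n <- length(ratios)
  if (n == 0) stop("tertile partition of an empty gene set")
  ord <- order(-ratios, names(ratios))
  ids <- names(ratios)[ord]
  if (n < 3) {
    warning("fewer than 3 genes; single-tertile fallback")
    sizes <- c(n, 0, 0)
  } else {
    base <- n %/% 3
    sizes <- rep(base, 3)
    extra <- n %% 3
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  tertile <- rep(c("ENHANCED", "NO_EFFECT", "ABROGATED"), times = sizes)
  out <- data.frame(feature_id = ids, ratio = unname(ratios[ord]),
                    rank = seq_len(n), tertile = tertile,
                    stringsAsFactors = FALSE)
  class(out) <- c("tertile_partition", "data.frame")
  out
}

#' Summarize category sizes in "x/y (z%)" form
#'
#' @param subset_n size of the subset (e.g. attenuated DMPs).
#' @param base_n size of the base set.
#' @return character scalar like \code{"312/7210 (4.3\%)"}; one decimal
#'   place, round-half-even.
#' @export
category_fraction <- function(subset_n, base_n) {
  format_fraction(subset_n, base_n)
}

#' @export
print.category_set <- function(x, ...) {
  cat("category_set:", x$category[1] %||% "(empty)", "-", nrow(x),
      "features (GAIN", sum(x$direction == "GAIN"), "/ LOSS",
      sum(x$direction == "LOSS"), ")\n")
  invisible(x)
}
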