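#' Classify a chi torsion into t / g / -g conformers
#'
#' Side chains at the Qo site populate three rotameric states centred near
#' 180 (trans, `t`), +60 (`g`) and -60 (`-g`) degrees. The circle is
#' partitioned into three 120-degree bins around these centres: `t` for
#' |angle| >= 120, `g` for angles in [0, 120), `-g` for angles in (-120, 0).
#' Input is wrapped into (-180, 180] first, so the function is total.
#'
#' @param angle numeric vector of torsions in degrees.
#' @return character vector with values in `c("t", "g", "-g")`.
#' @export
#' @examples
#' classify_conformer(c(179, 60, -60, -120))
classify_conformer <- function(angle) {
  a <- wrap_angle(angle)
  out <- character(length(a))
  out[abs(a) >= 120] <- "t"
  out[a >= 0 & a < 120] <- "g"
  out[a > -120 & a < 0] <- "-g"
  out
}

## chi quartet atom names by residue type and chi index (standard side-chain
## torsion conventions; only the residue types surveyed here are listed).
chi_quartet <- function(resname, chi) {
  q <- switch(paste0(toupper(resname), ".", chi),
    "TYR.1" = c("N", "CA", "CB", "CG"),
    "GLU.1" = c("N", "CA", "CB", "CG"),
    "HIS.1" = c("N", "CA", "CB", "CG"),
    "ASP.1" = c("N", "CA", "CB", "CG"),
    "TYR.2" = c("CA", "CB", "CG", "CD1"),
    "GLU.2" = c("CA", "CB", "CG", "CD"),
    "HIS.2" = c("CA", "CB", "CG", "ND1"),
    "ASP.2" = c("CA", "CB", "CG", "OD1"),
    NULL)
  if (is.null(q))
    stop("no chi", chi, " quartet defined for residue type ", resname,
         call. = FALSE)
  q
}

#' Compute a chi torsion of one residue in a model
#'
#' @param model a `qw_model`.
#' @param chain,resid residue address.
#' @param resname residue type (selects the quartet).
#' @param chi 1 or 2.
#' @return torsion in degrees, (-180, 180].
#' @export
residue_chi <- function(model, chain, resid, resname, chi = 1) {
  q <- chi_quartet(resname, chi)
  xyz <- lapply(q, function(a) atom_coord(model, chain, resid, a))
  dihedral_angle(xyz[[1]], xyz[[2]], xyz[[3]], xyz[[4]])
}

## The four torsions tabulated in the survey, in tuple order.
survey_torsions <- function() {
  data.frame(role = c("Y147", "E295", "E295", "Y297"),
             resname = c("TYR", "GLU", "GLU", "TYR"),
             chi = c(1L, 1L, 2L, 1L),
             label = c("Y147.chi1", "E295.chi1", "E295.chi2", "Y297.chi1"),
             stringsAsFactors = FALSE)
}

#' Survey joint torsional modes over a model ensemble
#'
#' For every model, computes the (Y147 chi1, E295 chi1, E295 chi2, Y297 chi1)
#' torsions via the residue map, classifies each into t/g/-g, and tabulates
#' the joint conformer tuples. Modes are sorted by descending count and
#' labelled A, B, C, ... with ties broken by lexicographic tuple order, so
#' the labelling is invariant under input permutation. Models missing a
#' mapping or an atom are reported in `skipped` with the reason, never
#' silently dropped.
#'
#' @param models list of `qw_model`.
#' @param map a `qw_residue_map` covering roles Y147, E295, Y297.
#' @return list with `modes` (data.frame: mode, the four conformer columns,
#'   count), `assignments` (per-model torsions, tuple, mode letter) and
#'   `skipped` (data.frame model_id, reason).
#' @export
survey_modes <- function(models, map) {
  if (length(models) == 0L) stop("no models supplied", call. = FALSE)
  tor <- survey_torsions()
  rows <- list(); skipped <- list()
  for (mod in models) {
    res <- try({
      ang <- vapply(seq_len(nrow(tor)), function(i) {
        e <- map_entry(map, mod$model_id, tor$role[i])
        if (is.null(e))
          stop("role ", tor$role[i], " not mapped for model ", mod$model_id,
               call. = FALSE)
        residue_chi(mod, e$chain, e$resid, tor$resname[i], tor$chi[i])
      }, numeric(1))
      ang
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(model_id = mod$model_id,
                   reason = trimws(conditionMessage(attr(res, "condition"))),
                   stringsAsFactors = FALSE)
      next
    }
    lab <- classify_conformer(res)
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = mod$model_id,
      t(stats::setNames(res, tor$label)),
      tuple = paste(lab, collapse = ","),
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model_id = character(), tuple = character())
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(model_id = character(), reason = character())

  tab <- table(assignments$tuple)
  ord <- order(-as.integer(tab), names(tab))
  tuples <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  modes <- data.frame(mode = LETTERS[seq_along(tuples)],
                      do.call(rbind, strsplit(tuples, ",", fixed = TRUE)),
                      count = counts, stringsAsFactors = FALSE)
  if (nrow(modes)) names(modes)[2:5] <- tor$label
  assignments$mode <- modes$mode[match(assignments$tuple, tuples)]
  list(modes = modes, assignments = assignments, skipped = skipped)
}

#' Count resolved waters near a centre
#'
#' Number of distinct water oxygens whose minimum distance to any atom of
#' the centre selection is below `radius` (strict). Experimental models are
#' treated non-periodically.
#'
#' @param model a `qw_model` with resolved waters.
#' @param center n x 3 coordinate matrix (nm) of the centre selection.
#' @param radius nm, > 0.
#' @return integer count.
#' @export
count_waters_near <- function(model, center, radius) {
  if (!isTRUE(model$has_waters))
    stop("model ", model$model_id, " has no resolved waters", call. = FALSE)
  stopifnot(radius > 0)
  if (is.null(dim(center))) center <- matrix(center, ncol = 3L)
  w <- water_oxygens(model)
  if (nrow(w) == 0L) return(0L)
  d2 <- rep(Inf, nrow(w))
  for (i in seq_len(nrow(center)))
    d2 <- pmin(d2, dist2_point_set(center[i, ], w))
  sum(d2 < radius^2)
}

#' Key quinone-bound distances of one model
#'
#' The two descriptors of the Q-bound pose: the H152 N-epsilon to Q-head O4
#' distance and the Y147 hydroxyl to Q-head O1 distance (nm).
#'
#' @param model a `qw_model` with a bound quinone.
#' @param map residue map providing roles H152, Y147 and Q_head.
#' @return named numeric vector `c(H152NE2_QO4 = , Y147OH_QO1 = )` in nm.
#' @export
qbound_distances <- function(model, map) {
  roles <- list(H152 = "NE2", Y147 = "OH")
  qe <- map_entry(map, model$model_id, "Q_head")
  if (is.null(qe)) stop("Q_head not mapped for model ", model$model_id,
                        call. = FALSE)
  o4 <- atom_coord(model, qe$chain, qe$resid, "O4")
  o1 <- atom_coord(model, qe$chain, qe$resid, "O1")
  he <- map_entry(map, model$model_id, "H152")
  ye <- map_entry(map, model$model_id, "Y147")
  if (is.null(he) || is.null(ye))
    stop("H152/Y147 not mapped for model ", model$model_id, call. = FALSE)
  d <- c(H152NE2_QO4 = pair_distance(atom_coord(model, he$chain, he$resid, "NE2"), o4),
         Y147OH_QO1 = pair_distance(atom_coord(model, ye$chain, ye$resid, "OH"), o1))
  if (any(!is.finite(d))) stop("non-finite Q-bound distance", call. = FALSE)
  d
}

#' Write survey outputs as TSV
#'
#' Emits the per-model assignment table and the mode summary, each with a
#' commented header recording the conformer-bin and altloc conventions.
#'
#' @param survey result of [survey_modes()].
#' @param assignments_path,modes_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_survey <- function(survey, assignments_path, modes_path) {
  hdr <- c("# qowire structure survey",
           "# conformer bins: t |chi|>=120, g [0,120), -g (-120,0) degrees",
           "# altlocs: highest occupancy kept; waters: resname HOH/WAT/H2O, O atoms")
  for (p in list(list(assignments_path, survey$assignments),
                 list(modes_path, survey$modes))) {
    con <- file(p[[1]], "w"); writeLines(hdr, con)
    utils::write.table(p[[2]], con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(assignments_path, modes_path))
}
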