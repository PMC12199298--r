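## StructureModel: one monomer model of the Qo site.
## atoms: data.frame(chain, resid, resname, atom, x, y, z, occ) with
## coordinates in nm. Waters are rows with resname in water_resnames().

water_resnames <- function() c("HOH", "WAT", "H2O", "SOL", "TIP3")

#' Construct a structure model
#'
#' @param model_id unique identifier (conventionally PDB id + chain + model
#'   number, e.g. "2qjp_A_1", or a synthetic tag).
#' @param atoms data.frame with columns chain, resid, resname, atom, x, y, z
#'   (nm) and optionally occ (occupancy, default 1).
#' @param method one of "x-ray", "cryo-em", "synthetic".
#' @return an object of class `qw_model`.
#' @export
structure_model <- function(model_id, atoms, method = "synthetic") {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  need <- c("chain", "resid", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  method <- match.arg(method, c("x-ray", "cryo-em", "synthetic"))
  w <- atoms$resname %in% water_resnames()
  structure(list(model_id = model_id, atoms = atoms, method = method,
                 has_waters = any(w)),
            class = "qw_model")
}

#' @export
print.qw_model <- function(x, ...) {
  cat("Qo-site structure model", x$model_id, "(", x$method, "):",
      nrow(x$atoms), "atoms,",
      sum(x$atoms$resname %in% water_resnames() & x$atoms$atom == "O"),
      "waters\n")
  invisible(x)
}

## Resolve (chain, resid, atom-name) to a coordinate row. Exactly one match
## required; alt-locs must already be collapsed (see read_structure_models).
atom_coord <- function(model, chain, resid, atom) {
  at <- model$atoms
  hit <- which(at$chain == chain & at$resid == resid & at$atom == atom)
  if (length(hit) == 0L)
    stop(sprintf("atom %s/%s/%s not found in model %s",
                 chain, resid, atom, model$model_id), call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf("atom %s/%s/%s ambiguous in model %s",
                 chain, resid, atom, model$model_id), call. = FALSE)
  c(at$x[hit], at$y[hit], at$z[hit])
}

## Coordinates of all water oxygens (n x 3, nm).
water_oxygens <- function(model) {
  at <- model$atoms
  sel <- at$resname %in% water_resnames() & at$atom %in% c("O", "OW", "OH2")
  as.matrix(at[sel, c("x", "y", "z")])
}

#' Read structure models from PDB/mmCIF files
#'
#' Each MODEL record of a multi-model file becomes one `qw_model`; for
#' single-model files with several protein chains, one model per chain is
#' emitted when `split_chains = TRUE` (waters are attached to every chain
#' model since crystallographic waters are not chain-assigned consistently).
#' Alternate locations are collapsed to the highest-occupancy altloc before
#' anything else is computed. Coordinates are converted from Angstrom to nm.
#'
#' @param files character vector of .pdb/.ent/.cif paths.
#' @param method structure method recorded on each model.
#' @param split_chains expand one model per protein chain (how dimeric
#'   entries contribute two Qo-site models each).
#' @return list of `qw_model`.
#' @export
read_structure_models <- function(files, method = "x-ray", split_chains = TRUE) {
  out <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    pdb <- if (ext == "cif") bio3d::read.cif(f, verbose = FALSE)
           else bio3d::read.pdb(f, verbose = FALSE, multi = TRUE)
    nmod <- max(1L, nrow(pdb$xyz))
    base <- sub("\\.(pdb|ent|cif)$", "", basename(f), ignore.case = TRUE)
    for (m in seq_len(nmod)) {
      at <- pdb$atom
      xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
      df <- data.frame(chain = as.character(at$chain),
                       resid = at$resno,
                       resname = as.character(at$resid),
                       atom = as.character(at$elety),
                       x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
                       occ = if (is.null(at$o)) 1 else at$o,
                       alt = if (is.null(at$alt)) NA_character_
                             else as.character(at$alt),
                       stringsAsFactors = FALSE)
      df <- collapse_altlocs(df)
      df$alt <- NULL
      if (split_chains) {
        wsel <- df$resname %in% water_resnames()
        chains <- unique(df$chain[!wsel])
        for (ch in chains) {
          sub <- rbind(df[!wsel & df$chain == ch, ], df[wsel, ])
          out[[length(out) + 1L]] <-
            structure_model(sprintf("%s_%s_%d", base, ch, m), sub, method)
        }
      } else {
        out[[length(out) + 1L]] <-
          structure_model(sprintf("%s_%d", base, m), df, method)
      }
    }
  }
  out
}

## Keep the highest-occupancy altloc per (chain, resid, atom); ties go to the
## alphabetically first altloc for determinism.
collapse_altlocs <- function(df) {
  if (all(is.na(df$alt) | df$alt %in% c("", " ", "."))) return(df)
  key <- paste(df$chain, df$resid, df$atom, sep = "\r")
  alt <- ifelse(is.na(df$alt) | df$alt %in% c("", " ", "."), "", df$alt)
  ord <- order(key, -df$occ, alt)
  df <- df[ord, ]
  df[!duplicated(key[ord]), ]
}

#' Read a residue map
#'
#' Cross-organism residue numbering differs, so the mapping from Qo-site
#' roles (Y147, E295, Y297, H276, D278, H152, PRA_bL, Q_head) to concrete
#' (chain, residue number) entries is curated input, not computation. The
#' TSV has columns model_id, role, chain, resid; a role may be marked absent
#' for a model by resid = NA.
#'
#' @param path TSV file path.
#' @return a `qw_residue_map`: named list model_id -> role -> list(chain, resid).
#' @export
read_residue_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("model_id", "role", "chain", "resid")
  if (!all(need %in% names(df)))
    stop("residue map needs columns ", paste(need, collapse = ", "), call. = FALSE)
  residue_map(df)
}

#' Build a residue map from a data.frame
#'
#' @param df data.frame with columns model_id, role, chain, resid.
#' @return a `qw_residue_map`.
#' @export
residue_map <- function(df) {
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$model_id[i])
    if (is.null(out[[id]])) out[[id]] <- list()
    out[[id]][[as.character(df$role[i])]] <-
      list(chain = as.character(df$chain[i]), resid = df$resid[i])
  }
  structure(out, class = "qw_residue_map")
}

## Look up a role for a model; "*" entries apply to every model.
map_entry <- function(map, model_id, role) {
  e <- map[[model_id]][[role]]
  if (is.null(e)) e <- map[["*"]][[role]]
  if (is.null(e) || is.na(e$resid)) return(NULL)
  e
}
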