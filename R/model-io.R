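# Pseudoatom models on disk: a PDB file (one HETATM per grain, residue PSE,
# element C) plus a plain-text sidecar holding what PDB fixed-width columns
# cannot: full-precision weights, sigma_voxels and voxel_size. The occupancy
# column carries the weight normalized by the maximum (clamped to [0,1]); the
# B-factor column carries the raw weight capped at 999.99.

sidecar_path <- function(path) {
  stem <- sub("\\.[^.]*$", "", basename(path))
  file.path(dirname(path), paste0(stem, ".pseudo.txt"))
}

hetatm_lines <- function(model) {
  n <- n_pseudoatoms(model)
  occ <- pmin(pmax(model$weights / max(model$weights), 0), 1)
  bfac <- pmin(model$weights, 999.99)
  sprintf("HETATM%5d  C   PSE A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          seq_len(n), seq_len(n),
          model$positions[, 1], model$positions[, 2], model$positions[, 3],
          occ, bfac)
}

#' Write a pseudoatom model as PDB plus sidecar
#'
#' Writes one `HETATM` record per pseudoatom (coordinates in Angstrom at the
#' PDB's 3-decimal precision), occupancy = weight / max(weight), B-factor =
#' raw weight capped at 999.99, and a sidecar text file (same stem,
#' `.pseudo.txt`) with a header line `sigma_voxels voxel_size N` followed by
#' one full-precision weight per line. [read_model()] restores weights
#' exactly from the sidecar.
#'
#' @param model A [pseudoatom_model].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pseudoatom_model"))
  n <- n_pseudoatoms(model)
  if (n > 99999L)
    stop("PDB serial field cannot hold more than 99999 pseudoatoms",
         call. = FALSE)
  header <- sprintf("REMARK   3 PSEUDOATOM MODEL  N=%d  SIGMA_VOXELS=%.6g", n,
                    model$sigma_voxels)
  writeLines(c(header, hetatm_lines(model), "END"), path)
  writeLines(c(sprintf("%.17g %.17g %d", model$sigma_voxels,
                       model$voxel_size, n),
               sprintf("%.17g", model$weights)),
             sidecar_path(path))
  invisible(path)
}

#' Read a pseudoatom model from PDB (+ sidecar)
#'
#' Positions come from the atom records (parsed with \pkg{bio3d}). If the
#' `.pseudo.txt` sidecar is present, weights, `sigma_voxels` and
#' `voxel_size` are restored at full precision; otherwise weights fall back
#' to the B-factor column and kernel geometry to `sigma_voxels = 1.5`,
#' `voxel_size = 1`, with a warning.
#'
#' @param path PDB file path.
#' @return A [pseudoatom_model].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) NULL)
  if (is.null(pdb) || nrow(pdb$atom) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  pos <- as.matrix(pdb$atom[, c("x", "y", "z")])
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    txt <- readLines(sc)
    head_fields <- as.numeric(strsplit(trimws(txt[1]), "\\s+")[[1]])
    weights <- as.numeric(txt[-1])
    if (length(weights) != nrow(pos))
      stop("sidecar weight count does not match atom records", call. = FALSE)
    pseudoatom_model(pos, weights, sigma_voxels = head_fields[1],
                     voxel_size = head_fields[2])
  } else {
    warning("no sidecar found for ", path,
            ": using B-factor column as weights and default kernel geometry")
    pseudoatom_model(pos, pdb$atom$b, sigma_voxels = 1.5, voxel_size = 1)
  }
}

#' Write a trajectory as a multi-model PDB
#'
#' Each frame becomes one `MODEL`/`ENDMDL` block, the standard animation
#' format for molecular viewers.
#'
#' @param frames List of [pseudoatom_model] objects.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "pseudoatom_model")))
  lines <- unlist(lapply(seq_along(frames), function(i) {
    c(sprintf("MODEL     %4d", i), hetatm_lines(frames[[i]]), "ENDMDL")
  }))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
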