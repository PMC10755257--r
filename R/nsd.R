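#' Least-squares rigid superposition onto the reference (Kabsch)
#'
#' Fits the 25-atom skeleton of a heme onto the reference by the
#' RMSD-minimizing proper rotation + translation (unweighted, all 25
#' atoms). Reflections are never applied: the rotation determinant is
#' always +1, so a mirror-image input keeps a positive residual rather
#' than being silently flipped.
#'
#' @param x A `heme_entry`, `porphyrin_ref` or named 25 x 3 matrix
#'   (the moving structure).
#' @param ref The target `porphyrin_ref`.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3; fitted = x %*% t(rotation) +
#'   translation after centering conventions are folded in), `rmsd`
#'   (Angstrom) and `fitted` (25 x 3 matrix).
#' @export
superpose <- function(x, ref) {
  X <- skeleton_xyz(x)
  Y <- skeleton_xyz(ref)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (any(svd(Xc)$d[1:2] < 1e-9))
    stop("fit error: degenerate (collinear or coincident) coordinates")
  C <- crossprod(Xc, Yc)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  fitted <- sweep(fitted, 2, cy, "+")
  rownames(fitted) <- rownames(Y)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R,
                 translation = as.vector(cy - R %*% cx),
                 rmsd = rmsd, fitted = fitted),
            class = "superposition")
}

#' Displacement vector of a fitted heme from the reference
#'
#' @param fitted 25 x 3 fitted coordinates (from [superpose()]).
#' @param ref The `porphyrin_ref`.
#' @return Numeric vector of length 75, atom-major (x, y, z per atom).
#' @export
displacement_vector <- function(fitted, ref) {
  if (is.list(fitted) && !is.null(fitted$fitted)) fitted <- fitted$fitted
  d <- xyz_to_vec(skeleton_xyz(fitted) - skeleton_xyz(ref))
  if (any(!is.finite(d))) stop("non-finite displacement")
  d
}

#' Project a displacement onto the 12-mode NSD basis
#'
#' Each amplitude is the plain inner product of the unit mode vector
#' with the displacement (no mass weighting, no pseudo-inverse: the
#' basis is used exactly as normalized, "almost orthogonal").
#'
#' @param d Displacement vector of length 75 (Angstrom), or a
#'   `superposition` together with `ref`.
#' @param basis A `mode_basis`.
#' @param rmsd Optional fit RMSD to carry along.
#' @return Object of class `nsd_result`: list with `d` (named numeric,
#'   signed amplitudes in Angstrom for the 12 modes), `rmsd`,
#'   `oop_total` and `ip_total` (root-sum-of-squares over the
#'   out-of-plane and in-plane mode groups).
#' @export
project_modes <- function(d, basis, rmsd = NA_real_) {
  if (length(d) != nrow(basis$vectors))
    stop("dimension error: displacement has length ", length(d),
         ", basis expects ", nrow(basis$vectors))
  amps <- as.vector(crossprod(basis$vectors, d))
  names(amps) <- colnames(basis$vectors)
  oop <- oop_mode_names()
  structure(list(d = amps, rmsd = rmsd,
                 oop_total = sqrt(sum(amps[oop]^2)),
                 ip_total = sqrt(sum(amps[setdiff(names(amps), oop)]^2))),
            class = "nsd_result")
}

#' @export
print.nsd_result <- function(x, ...) {
  cat("NSD amplitudes (Angstrom):\n")
  print(round(x$d, 4))
  cat("fit RMSD:", format(round(x$rmsd, 4)),
      " out-of-plane total:", round(x$oop_total, 4),
      " in-plane total:", round(x$ip_total, 4), "\n")
  invisible(x)
}

#' Full NSD pipeline for one heme
#'
#' Superpose the skeleton on the reference, form the displacement, and
#' project it onto the 12-mode basis.
#'
#' @param heme A `heme_entry` (or 25 x 3 named coordinate matrix).
#' @param ref A `porphyrin_ref`.
#' @param basis A `mode_basis`.
#' @return An `nsd_result`.
#' @export
#' @examples
#' \donttest{
#' ref <- build_reference_porphine()
#' basis <- build_mode_basis(ref)
#' nsd_pipeline(ref, ref, basis)$d   # all zero on the reference itself
#' }
nsd_pipeline <- function(heme, ref, basis) {
  sup <- superpose(heme, ref)
  project_modes(displacement_vector(sup$fitted, ref), basis, rmsd = sup$rmsd)
}

#' NSD amplitudes for a list of hemes as a data frame
#'
#' @param hemes List of `heme_entry` objects.
#' @param ref,basis Reference structure and mode basis.
#' @return data.frame: one row per heme, identity columns, the 12 mode
#'   amplitudes and the fit RMSD.
#' @export
nsd_table <- function(hemes, ref, basis) {
  rows <- lapply(hemes, function(h) {
    r <- nsd_pipeline(h, ref, basis)
    id <- if (inherits(h, "heme_entry"))
      data.frame(pdb_id = h$pdb_id, asym_id = h$asym_id,
                 chain_id = h$chain_id, residue_index = h$residue_index,
                 comp_id = h$comp_id, stringsAsFactors = FALSE)
    else data.frame(pdb_id = NA_character_, asym_id = NA_character_,
                    chain_id = NA_character_, residue_index = NA_integer_,
                    comp_id = NA_character_, stringsAsFactors = FALSE)
    cbind(id, as.data.frame(as.list(r$d)), rmsd = r$rmsd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
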