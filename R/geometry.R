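#' @include AllClasses.R structure-io.R
NULL

# Kabsch: optimal proper rotation R and translation t with
# x_fitted = R (x - center_P) + center_Q minimizing RMSD(P -> Q).
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))  # 3x3
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_P = cp, center_Q = cq,
       t = as.numeric(cq - R %*% cp))
}

.apply_rt <- function(xyz, fit) {
  sweep(xyz %*% t(fit$R), 2, fit$t, `+`)
}

.check_selection <- function(P, Q) {
  if (!is.matrix(P) || !is.matrix(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("selections must be n x 3 coordinate matrices")
  if (nrow(P) != nrow(Q))
    stop("selections must have equal numbers of corresponding atoms")
  if (nrow(P) < 3L)
    stop("superposition requires >= 3 corresponding atoms")
  s <- svd(sweep(P, 2, colMeans(P)))$d
  if (s[2] < 1e-8 * max(s[1], 1))
    stop("selection is collinear; superposition is underdetermined")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal proper rotation (reflections excluded) and translation mapping the
#' mobile coordinates onto the reference, with the residual RMSD over the
#' correspondence. Inputs are either n x 3 coordinate matrices or
#' \linkS4class{StructureModel} objects with atom-index selections.
#'
#' @param mobile,reference coordinate matrices or StructureModels.
#' @param sel_mobile,sel_reference atom indices (as from
#'   \code{\link{selectAtoms}}) when models are passed; must correspond
#'   one-to-one in order.
#' @return a \linkS4class{Superposition}; the fitted mobile coordinates
#'   satisfy \code{x' = R x + t}.
#' @export
superpose <- function(mobile, reference, sel_mobile = NULL,
                      sel_reference = NULL) {
  P <- if (is(mobile, "StructureModel")) coords(mobile, sel_mobile)
       else as.matrix(mobile)
  Q <- if (is(reference, "StructureModel")) coords(reference, sel_reference)
       else as.matrix(reference)
  .check_selection(P, Q)
  fit <- .kabsch(P, Q)
  fitted <- .apply_rt(P, fit)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  new("Superposition", rotation = fit$R, translation = fit$t, rmsd = rmsd,
      n_pairs = nrow(P))
}

#' Apply a superposition to coordinates or a whole model
#'
#' @param sp a \linkS4class{Superposition}.
#' @param x an n x 3 matrix or a \linkS4class{StructureModel}.
#' @return the transformed matrix or model.
#' @export
applySuperposition <- function(sp, x) {
  f <- list(R = sp@rotation, t = sp@translation)
  if (is(x, "StructureModel")) {
    a <- atoms(x)
    xyz <- .apply_rt(as.matrix(a[, c("x", "y", "z")]), f)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    x@atoms <- a
    return(x)
  }
  .apply_rt(as.matrix(x), f)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 proper rotation matrix.
#' @return angle in degrees, in [0, 180].
#' @export
rotationAngle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Residual rotation between two domains after frame alignment
#'
#' Superposes complex B onto complex A using the align selections (typically
#' receptor 7TM C-alpha atoms), then computes the optimal residual rotation
#' between the measure selections (typically chemokine-core C-alpha atoms)
#' and returns its angle. Invariant to any common rigid transform applied to
#' either whole complex beforehand.
#'
#' @param model_a,model_b \linkS4class{StructureModel} objects (or n x 3
#'   matrices, in which case the selections are row indices).
#' @param align_a,align_b corresponding atom indices defining the common
#'   frame.
#' @param measure_a,measure_b corresponding atom indices of the domain whose
#'   orientation difference is measured.
#' @return angle in degrees, in [0, 180].
#' @export
interdomainRotation <- function(model_a, model_b, align_a, align_b,
                                measure_a, measure_b) {
  getxyz <- function(m, sel) {
    if (is(m, "StructureModel")) coords(m, sel)
    else as.matrix(m)[sel, , drop = FALSE]
  }
  A_align <- getxyz(model_a, align_a)
  B_align <- getxyz(model_b, align_b)
  A_meas <- getxyz(model_a, measure_a)
  B_meas <- getxyz(model_b, measure_b)
  .check_selection(B_align, A_align)
  .check_selection(B_meas, A_meas)
  frame <- .kabsch(B_align, A_align)
  B_meas_in_A <- .apply_rt(B_meas, frame)
  resid <- .kabsch(B_meas_in_A, A_meas)
  rotationAngle(resid$R)
}

#' Chemokine-core C-alpha correspondence between two complexes
#'
#' Builds a residue correspondence between the chemokine chains of two
#' complexes, anchored at the first conserved core cysteine (the CC motif):
#' residue i of chemokine A pairs with residue i - offset of chemokine B,
#' where the offset aligns the first cysteines. Only residues with a C-alpha
#' in both models are paired.
#'
#' @param model_a,model_b annotated \linkS4class{StructureModel} objects with
#'   chemokine chain roles.
#' @return list with integer atom-index vectors \code{a} and \code{b}
#'   (corresponding C-alpha atoms).
#' @export
chemokineCoreCorrespondence <- function(model_a, model_b) {
  grab <- function(m) {
    roles <- chainRoles(m)
    ch <- names(roles)[roles == "chemokine"]
    if (!length(ch)) stop("model lacks a chemokine chain role")
    a <- atoms(m)
    ca <- which(a$chain %in% ch & a$name == "CA" & !a$het)
    cys <- sort(unique(a$resno[a$chain %in% ch & a$resid == "CYS" & !a$het]))
    if (!length(cys)) stop("chemokine chain has no cysteines to anchor on")
    list(ca = ca, resno = a$resno[ca], anchor = cys[1])
  }
  A <- grab(model_a)
  B <- grab(model_b)
  offset <- A$anchor - B$anchor
  common <- intersect(A$resno, B$resno + offset)
  if (length(common) < 3L)
    stop("chemokine-core correspondence has fewer than 3 residue pairs")
  list(a = A$ca[match(common, A$resno)],
       b = B$ca[match(common - offset, B$resno)])
}

# ring atoms used for aromatic side-chain direction vectors
.ring_atoms <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                            "CZ2", "CZ3", "CH2"),
                    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.sidechain_vector <- function(a, resno, chain, label) {
  res <- a[a$chain == chain & a$resno == resno & !a$het, , drop = FALSE]
  if (!nrow(res)) stop("residue ", resno, " absent in ", label)
  resid <- res$resid[1]
  cb <- res[res$name == "CB", , drop = FALSE]
  if (!nrow(cb)) stop("residue ", resno, " (", resid, ") in ", label,
                      " lacks a CB atom")
  origin <- c(cb$x[1], cb$y[1], cb$z[1])
  if (resid %in% names(.ring_atoms)) {
    ring <- res[res$name %in% .ring_atoms[[resid]], , drop = FALSE]
    missing <- setdiff(.ring_atoms[[resid]], ring$name)
    if (length(missing))
      stop("residue ", resno, " (", resid, ") in ", label,
           " lacks ring atoms: ", paste(missing, collapse = ", "))
    tip <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
  } else {
    sc <- res[!res$name %in% c("N", "CA", "C", "O", "OXT", "CB") &
                !res$element %in% c("H", "D"), , drop = FALSE]
    if (!nrow(sc))
      stop("residue ", resno, " (", resid, ") in ", label,
           " has no side-chain heavy atoms beyond CB")
    ca <- res[res$name == "CA", , drop = FALSE]
    ref <- if (nrow(ca)) c(ca$x[1], ca$y[1], ca$z[1]) else origin
    d <- (sc$x - ref[1])^2 + (sc$y - ref[2])^2 + (sc$z - ref[3])^2
    k <- which.max(d)
    tip <- c(sc$x[k], sc$y[k], sc$z[k])
  }
  tip - origin
}

#' Side-chain sway angle between two structural states
#'
#' After superposing the local backbone (N, CA, C of the residue plus/minus
#' \code{flank} residues) of state B onto state A, measures the angle between
#' the two states' side-chain direction vectors: CB to ring centroid for
#' aromatic residues, CB to the most distal side-chain heavy atom otherwise.
#' The alternative \code{"chi"} method reports the absolute chi1
#' (N-CA-CB-CG) dihedral difference instead.
#'
#' @param model_a,model_b \linkS4class{StructureModel} objects of the two
#'   states.
#' @param resno residue number of interest.
#' @param chain chain id; default the (single) receptor-role chain.
#' @param flank backbone residues on each side used for the local frame.
#' @param method \code{"vector"} (default) or \code{"chi"}.
#' @return angle in degrees, in [0, 180].
#' @export
sidechainOrientationChange <- function(model_a, model_b, resno, chain = NULL,
                                       flank = 3L,
                                       method = c("vector", "chi")) {
  method <- match.arg(method)
  pick_chain <- function(m) {
    if (!is.null(chain)) return(chain)
    roles <- chainRoles(m)
    rec <- names(roles)[roles == "receptor"]
    if (length(rec) != 1L)
      stop("pass 'chain' explicitly when the receptor role is ambiguous")
    rec
  }
  ch_a <- pick_chain(model_a)
  ch_b <- pick_chain(model_b)
  a <- atoms(model_a)
  b <- atoms(model_b)
  if (method == "chi") {
    dihe <- function(at, ch) {
      res <- at[at$chain == ch & at$resno == resno & !at$het, , drop = FALSE]
      need <- c("N", "CA", "CB")
      got <- res[match(need, res$name), , drop = FALSE]
      cg <- res[grepl("^[COSN]G", res$name), , drop = FALSE]
      if (anyNA(got$name) || !nrow(cg))
        stop("residue ", resno, " lacks chi1 atoms (need N, CA, CB, *G)")
      p <- rbind(as.matrix(got[, c("x", "y", "z")]),
                 as.matrix(cg[1, c("x", "y", "z")]))
      .dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    }
    d <- abs(dihe(a, ch_a) - dihe(b, ch_b)) %% 360
    return(if (d > 180) 360 - d else d)
  }
  bb <- function(at, ch) {
    sel <- at$chain == ch & at$resno %in% (resno - flank):(resno + flank) &
      at$name %in% c("N", "CA", "C") & !at$het
    sub <- at[sel, , drop = FALSE]
    sub[order(sub$resno, match(sub$name, c("N", "CA", "C"))), , drop = FALSE]
  }
  bbA <- bb(a, ch_a)
  bbB <- bb(b, ch_b)
  key <- function(x) paste(x$resno, x$name)
  common <- intersect(key(bbA), key(bbB))
  if (length(common) < 3L)
    stop("insufficient common backbone atoms around residue ", resno)
  P <- as.matrix(bbB[match(common, key(bbB)), c("x", "y", "z")])
  Q <- as.matrix(bbA[match(common, key(bbA)), c("x", "y", "z")])
  fit <- .kabsch(P, Q)
  vA <- .sidechain_vector(a, resno, ch_a, "state A")
  vB <- .sidechain_vector(b, resno, ch_b, "state B")
  vB <- as.numeric(fit$R %*% vB)  # rotate into A's local frame
  cosang <- sum(vA * vB) / sqrt(sum(vA^2) * sum(vB^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
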