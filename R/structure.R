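# Whole-protein structural checks: alpha-helix assignment from backbone
# hydrogen bonding (Kabsch-Sander energy criterion), helix propensity and
# capping, disulfide bridges, and salt-bridge counting.

.KS_CONST <- 0.084 * 332      # kcal/mol * Angstrom, electrostatic H-bond model
.KS_CUTOFF <- -0.5            # kcal/mol
.SS_BOND_MAX <- 2.3           # Angstrom SG-SG distance for a disulfide
.SALT_BRIDGE_MAX <- 4.0       # Angstrom, strict less-than

#' Assign alpha-helices on the first frame
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' energy `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#' (bond if `E < -0.5`), and alpha-helices are built from runs of
#' consecutive i -> i+4 turns: two successive turns starting at `i-1` and
#' `i` make residues `i..i+3` helical.  Helices are assigned on frame 1
#' only and held fixed for the trajectory.
#'
#' @param ens a `structure_ensemble`.
#' @return data.frame of segments: chain, start, end (residue numbers,
#'   inclusive).
#' @export
assign_helices <- function(ens) {
  a <- ens$atoms
  xyz <- ens$frames[[1]]
  out <- list()
  for (ch in unique(a$chain[!a$is_water])) {
    resnos <- sort(unique(a$resno[a$chain == ch & !a$is_water]))
    getat <- function(r, nm) {
      i <- which(a$chain == ch & a$resno == r & a$name == nm & !a$is_water)
      if (length(i) == 0) return(NULL)
      xyz[i[1], ]
    }
    nres <- length(resnos)
    if (nres < 5) next
    # turn[i] : CO of residue resnos[i] accepts from NH of resnos[i+4]
    turn <- rep(FALSE, nres)
    for (i in seq_len(nres - 4)) {
      rC <- resnos[i]; rN <- resnos[i + 4]
      C <- getat(rC, "C"); O <- getat(rC, "O")
      N <- getat(rN, "N"); H <- getat(rN, "H")
      if (is.null(C) || is.null(O))
        stop(sprintf("residue %s:%d lacks backbone C/O atoms", ch, rC))
      if (is.null(N))
        stop(sprintf("residue %s:%d lacks a backbone N atom", ch, rN))
      if (is.null(H)) next   # proline or unprotonated N cannot donate
      e <- .KS_CONST * (1 / vnorm(O - N) + 1 / vnorm(C - H) -
                          1 / vnorm(O - H) - 1 / vnorm(C - N))
      turn[i] <- e < .KS_CUTOFF
    }
    helical <- rep(FALSE, nres)
    for (i in 2:max(2, nres - 4)) {
      if (i <= nres - 4 && turn[i - 1] && turn[i])
        helical[i:(i + 3)] <- TRUE
    }
    r <- rle(helical)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        chain = ch, start = resnos[starts[k]], end = resnos[ends[k]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, out)
}

#' Helix-propensity change of a mutation
#'
#' Returns the propensity penalty difference (mutant minus wild type,
#' kJ/mol) when the mutated position lies inside an assigned helix and at
#' least five positions from both helix termini; otherwise 0, so the check
#' stays independent of helix capping.
#'
#' @param mutation mutation specifier.
#' @param helices segment table from [assign_helices()].
#' @param scale propensity scale (named by 1-letter code, kJ/mol).
#' @return kJ/mol.
#' @export
propensity_delta <- function(mutation, helices,
                             scale = helix_propensity_scale()) {
  mut <- parse_mutation(mutation)
  if (any(is.na(scale[c(mut$wt, mut$mut)])))
    stop("propensity scale does not cover both residues")
  hit <- helices$chain == mut$chain & helices$start <= mut$pos &
    helices$end >= mut$pos
  if (!any(hit)) return(0)
  seg <- helices[which(hit)[1], ]
  if (mut$pos - seg$start < 5 || seg$end - mut$pos < 5) return(0)
  unname(scale[mut$mut] - scale[mut$wt])
}

# capping-motif roles; replaceable via the `motifs` argument
.CAP_MOTIFS <- list(n_cap = c("N", "D", "S", "T", "G"), c_cap = "G")

#' Check whether a mutation disrupts a helix-capping motif
#'
#' Positions within five residues of a helix terminus are checked against
#' the capping-role table (N-cap: Asn/Asp/Ser/Thr/Gly near the helix start;
#' C-cap: Gly near the helix end).  The flag is raised when the wild-type
#' residue fills such a role and the mutant residue does not preserve it.
#' The motif catalogue is an explicit approximation and can be replaced.
#'
#' @param mutation mutation specifier.
#' @param helices segment table from [assign_helices()].
#' @param window residues around a terminus that are checked (default 5).
#' @param motifs list with entries `n_cap` and `c_cap` of role residues.
#' @return logical flag.
#' @export
capping_check <- function(mutation, helices, window = 5,
                          motifs = .CAP_MOTIFS) {
  mut <- parse_mutation(mutation)
  segs <- helices[helices$chain == mut$chain, , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    near_n <- abs(mut$pos - segs$start[k]) <= window
    near_c <- abs(mut$pos - segs$end[k]) <= window
    if (near_n && mut$wt %in% motifs$n_cap && !(mut$mut %in% motifs$n_cap))
      return(TRUE)
    if (near_c && mut$wt %in% motifs$c_cap && !(mut$mut %in% motifs$c_cap))
      return(TRUE)
  }
  FALSE
}

#' Count disulfide bridges
#'
#' Cys-Cys pairs with an explicit SG-SG bond record; when the bond table is
#' silent on sulfur pairs, SG atoms closer than 2.3 Angstrom in frame 1 are
#' counted instead.
#'
#' @param ens a `structure_ensemble`.
#' @return integer count.
#' @export
disulfide_count <- function(ens) {
  a <- ens$atoms
  sg <- which(a$resname == "CYS" & a$name == "SG")
  if (length(sg) < 2) return(0L)
  b <- ens$bonds
  rec <- b[b[, 1] %in% sg & b[, 2] %in% sg, , drop = FALSE]
  if (nrow(rec) > 0) return(nrow(unique(rec)))
  xyz <- ens$frames[[1]]
  cnt <- 0L
  for (i in seq_along(sg)) for (j in seq_len(i - 1)) {
    if (vnorm(xyz[sg[i], ] - xyz[sg[j], ]) <= .SS_BOND_MAX) cnt <- cnt + 1L
  }
  cnt
}

#' @keywords internal
.charged_atoms <- function(ens) {
  a <- ens$atoms
  nb <- .bond_neighbors(ens)
  acid <- which((a$resname == "ASP" & a$name %in% .ACIDIC_O$ASP) |
                  (a$resname == "GLU" & a$name %in% .ACIDIC_O$GLU))
  basic <- which((a$resname == "LYS" & a$name %in% .BASIC_N$LYS) |
                   (a$resname == "ARG" & a$name %in% .BASIC_N$ARG))
  # histidine counts only when both ring nitrogens are protonated
  his <- unique(paste(a$chain, a$resno)[a$resname == "HIS"])
  for (key in his) {
    ring <- which(paste(a$chain, a$resno) == key & a$name %in% c("ND1", "NE2"))
    if (length(ring) == 2 &&
        all(vapply(ring, function(i) any(a$element[nb[[i]]] == "H"),
                   logical(1))))
      basic <- c(basic, ring)
  }
  list(acid = acid, basic = sort(basic))
}

#' Mean salt-bridge count over the trajectory
#'
#' A salt bridge is a sidechain carboxylate oxygen of Asp/Glu within (strictly
#' less than) 4 Angstrom of a charged sidechain nitrogen of Lys/Arg (or
#' doubly protonated His).  Contacts are counted once per residue pair and
#' frame, then frame-averaged; assessed on the whole protein.
#'
#' @param ens a `structure_ensemble`.
#' @return mean count per frame.
#' @export
salt_bridge_count <- function(ens) {
  a <- ens$atoms
  ch <- .charged_atoms(ens)
  if (length(ch$acid) == 0 || length(ch$basic) == 0) return(0)
  akey <- paste(a$chain, a$resno)
  per_frame <- vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- ens$frames[[f]]
    pairs <- character(0)
    for (i in ch$acid) {
      dd <- sqrt((xyz[ch$basic, 1] - xyz[i, 1])^2 +
                   (xyz[ch$basic, 2] - xyz[i, 2])^2 +
                   (xyz[ch$basic, 3] - xyz[i, 3])^2)
      hit <- ch$basic[dd < .SALT_BRIDGE_MAX]
      if (length(hit) > 0)
        pairs <- c(pairs, paste(akey[i], "|", akey[hit]))
    }
    length(unique(pairs))
  }, numeric(1))
  frame_average(per_frame)
}
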