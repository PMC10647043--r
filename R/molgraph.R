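# Internal molecular-graph layer.
#
# Structure perception (parsing, kekulization, aromaticity, formal charges,
# canonicalization) is delegated to OpenBabel via ChemmineOB/ChemmineR/bio3d;
# this file only holds the edited-graph representation that the transformation
# rules operate on, plus a kekulized SMILES writer able to place directional
# bonds around azo (N=N) groups. Every SMILES the writer emits is
# re-canonicalized through OpenBabel, which is the authority on validity.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source = text),
                  error = function(e) NULL)
  if (is.null(out) || !nzchar(out)) return(NULL)
  out
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparsable entries yield
#' \code{NA}. Vectorized; conversion is batched for speed.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where parsing fails.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(res)
  idx <- which(ok)
  input <- paste0(smiles[idx], "\tpswidx", seq_along(idx), collapse = "\n")
  out <- suppressWarnings(ob_convert("SMI", "CAN", paste0(input, "\n")))
  if (!is.null(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) >= 2 && grepl("^pswidx[0-9]+$", parts[2])) {
        k <- as.integer(sub("pswidx", "", parts[2]))
        res[idx[k]] <- parts[1]
      }
    }
  }
  # fall back to per-molecule conversion for any entries a batch failure lost
  for (k in idx[is.na(res[idx])]) {
    out1 <- suppressWarnings(ob_convert("SMI", "CAN", paste0(smiles[k], "\tx\n")))
    if (!is.null(out1)) {
      parts <- strsplit(trimws(out1), "[ \t]+")[[1]]
      if (length(parts) >= 1 && nzchar(parts[1])) res[k] <- parts[1]
    }
  }
  res
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Strip stereochemistry from SMILES
#'
#' Removes directional-bond and tetrahedral markers and re-canonicalizes,
#' giving a constitution-level key (used e.g. to verify that a trans/cis pair
#' shares one constitution).
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical constitution SMILES.
#' @export
strip_stereo <- function(smiles) {
  flat <- gsub("[/\\\\]", "", smiles)
  flat <- gsub("\\[C@+H\\]", "C", flat)
  flat <- gsub("@", "", flat, fixed = TRUE)
  canonical_smiles(flat)
}

# --- graph construction ------------------------------------------------------

#' Parse a SMILES string into an editable molecular graph
#'
#' Perception (kekulized bond orders, formal charges, aromatic flags, 2D
#' layout) comes from OpenBabel; atom order is the input SMILES atom order.
#' Pre-existing azo (aromatic-C-N=N-C-aromatic) bond geometry is recovered
#' from the 2D layout so it can be re-emitted unchanged.
#'
#' @param smiles a single SMILES string.
#' @return an object of class \code{psw_mol}, or \code{NULL} if parsing fails.
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  sdf_txt <- ob_convert("SMI", "SDF", paste0(smiles, "\tmol\n"))
  mol2_txt <- ob_convert("SMI", "MOL2", paste0(smiles, "\tmol\n"))
  if (is.null(sdf_txt) || is.null(mol2_txt)) return(NULL)

  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf_txt)))),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) < 1) return(NULL)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(n) || n == 0) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- cbind(ab[, 1], ab[, 2])

  charge <- integer(n)
  for (ln in grep("^M  CHG", strsplit(sdf_txt, "\n", fixed = TRUE)[[1]], value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", ln)), "\\s+")[[1]])
    if (length(flds) >= 2) {
      pairs <- matrix(flds, ncol = 2, byrow = TRUE)
      charge[pairs[, 1]] <- pairs[, 2]
    }
  }

  if (nrow(bb) > 0) {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  # aromatic bonds from the MOL2 export (same atom order)
  f <- tempfile(fileext = ".mol2")
  on.exit(unlink(f), add = TRUE)
  writeLines(mol2_txt, f)
  m2 <- tryCatch(bio3d::read.mol2(f), error = function(e) NULL)
  arom_bond <- rep(FALSE, nrow(bonds))
  if (!is.null(m2) && !is.null(m2$bond) && nrow(m2$bond) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ar <- m2$bond$type == "ar"
    arkeys <- key(m2$bond$origin[ar], m2$bond$target[ar])
    arom_bond <- key(bonds$a1, bonds$a2) %in% arkeys
  }
  arom_atom <- rep(FALSE, n)
  arom_atom[unique(c(bonds$a1[arom_bond], bonds$a2[arom_bond]))] <- TRUE
  bonds$arom <- arom_bond

  mol <- structure(list(
    atoms = data.frame(elem = elem, charge = charge, arom = arom_atom,
                       parent_idx = seq_len(n), stringsAsFactors = FALSE),
    bonds = bonds,
    coords = coords,
    smiles_in = smiles,
    azo_geom = list()
  ), class = "psw_mol")
  mol$azo_geom <- .detect_azo_geometry(mol)
  mol
}

# geometry of pre-existing azo bonds, from the 2D layout OpenBabel produced
# (the layout honors input directional bonds). Returns list keyed "i-j".
.detect_azo_geometry <- function(mol) {
  out <- list()
  for (m in find_azo_motifs(mol)) {
    c1 <- mol$coords[m["c1"], ]; n1 <- mol$coords[m["n1"], ]
    n2 <- mol$coords[m["n2"], ]; c2 <- mol$coords[m["c2"], ]
    ax <- n2 - n1
    s1 <- ax[1] * (c1[2] - n1[2]) - ax[2] * (c1[1] - n1[1])
    s2 <- ax[1] * (c2[2] - n1[2]) - ax[2] * (c2[1] - n1[1])
    if (abs(s1) < 1e-8 || abs(s2) < 1e-8) next
    out[[paste(m["n1"], m["n2"], sep = "-")]] <-
      if (sign(s1) == sign(s2)) "Z" else "E"
  }
  out
}

# --- basic queries -----------------------------------------------------------

mol_n_atoms <- function(mol) nrow(mol$atoms)

mol_neighbors <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

mol_bond_between <- function(mol, i, j) {
  which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
        (mol$bonds$a1 == j & mol$bonds$a2 == i))
}

mol_degree <- function(mol, i) length(mol_neighbors(mol, i))

mol_bondsum <- function(mol, i) {
  sum(mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i])
}

#' @keywords internal
heavy_atom_count <- function(mol) {
  if (inherits(mol, "psw_mol")) sum(mol$atoms$elem != "H") else NA_integer_
}

# ring membership: a bond is in a ring iff it is not a bridge of the
# heavy-atom graph; an atom is in a ring iff it has an in-ring incident bond.
mol_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  br <- igraph::bridges(g)
  inring <- rep(TRUE, nb)
  inring[as.integer(br)] <- FALSE
  inring
}

mol_ring_atoms <- function(mol) {
  rb <- mol_ring_bonds(mol)
  at <- rep(FALSE, mol_n_atoms(mol))
  at[unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))] <- TRUE
  at
}

# size of the smallest ring containing the bond i-j (Inf if acyclic)
mol_smallest_ring_through <- function(mol, i, j) {
  b <- mol_bond_between(mol, i, j)
  if (length(b) == 0) return(Inf)
  # BFS from i to j avoiding bond b
  n <- mol_n_atoms(mol)
  dist <- rep(Inf, n)
  dist[i] <- 0
  queue <- i
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (k in seq_len(nrow(mol$bonds))) {
      if (k == b) next
      uu <- mol$bonds$a1[k]; vv <- mol$bonds$a2[k]
      v <- if (uu == u) vv else if (vv == u) uu else next
      if (dist[v] > dist[u] + 1) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist[j] + 1
}

#' Locate aromatic azo motifs
#'
#' Finds every aromatic-C(ring)-N=N-C(ring)-aromatic substructure: an N=N
#' double bond between two acyclic nitrogens, each bonded to exactly one
#' other heavy atom, which is aromatic.
#'
#' @param mol a \code{psw_mol}.
#' @return list of named integer vectors (c1, n1, n2, c2).
#' @export
find_azo_motifs <- function(mol) {
  out <- list()
  ringb <- mol_ring_bonds(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] != 2 || isTRUE(ringb[k])) next
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (mol$atoms$elem[i] != "N" || mol$atoms$elem[j] != "N") next
    ni <- setdiff(mol_neighbors(mol, i), j)
    nj <- setdiff(mol_neighbors(mol, j), i)
    if (length(ni) != 1 || length(nj) != 1) next
    if (!mol$atoms$arom[ni] || !mol$atoms$arom[nj]) next
    out[[length(out) + 1]] <- c(c1 = ni, n1 = i, n2 = j, c2 = nj)
  }
  out
}

#' Count aromatic azo motifs in a SMILES
#' @param smiles a single SMILES string.
#' @return integer count (NA if unparsable).
#' @export
count_azo_motifs <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  if (is.null(mol)) return(NA_integer_)
  length(find_azo_motifs(mol))
}

# --- graph editing -----------------------------------------------------------

# delete atoms (and incident bonds); provenance and azo geometry keys remapped
mol_delete_atoms <- function(mol, idx) {
  if (length(idx) == 0) return(mol)
  keep <- setdiff(seq_len(mol_n_atoms(mol)), idx)
  remap <- integer(mol_n_atoms(mol))
  remap[keep] <- seq_along(keep)
  bkeep <- !(mol$bonds$a1 %in% idx | mol$bonds$a2 %in% idx)
  newgeom <- list()
  for (key in names(mol$azo_geom)) {
    ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    if (!any(ij %in% idx))
      newgeom[[paste(remap[ij[1]], remap[ij[2]], sep = "-")]] <- mol$azo_geom[[key]]
  }
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$coords <- mol$coords[keep, , drop = FALSE]
  mol$bonds <- mol$bonds[bkeep, , drop = FALSE]
  mol$bonds$a1 <- remap[mol$bonds$a1]
  mol$bonds$a2 <- remap[mol$bonds$a2]
  rownames(mol$bonds) <- NULL
  mol$azo_geom <- newgeom
  mol
}

mol_add_atom <- function(mol, elem, charge = 0L, arom = FALSE) {
  mol$atoms <- rbind(mol$atoms, data.frame(elem = elem, charge = as.integer(charge),
                                           arom = arom, parent_idx = NA_integer_,
                                           stringsAsFactors = FALSE))
  mol$coords <- rbind(mol$coords, c(0, 0))
  mol
}

mol_add_bond <- function(mol, a1, a2, order = 1L, arom = FALSE) {
  mol$bonds <- rbind(mol$bonds, data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
                                           order = as.integer(order), arom = arom))
  mol
}

# delete the branch hanging off `root` through neighbor `branch_start`
# (connected component of branch_start after removing root); returns atom ids
branch_atoms <- function(mol, root, branch_start) {
  seen <- c(branch_start)
  queue <- branch_start
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in mol_neighbors(mol, u)) {
      if (v != root && !(v %in% seen)) {
        seen <- c(seen, v)
        queue <- c(queue, v)
      }
    }
  }
  sort(seen)
}

# --- SMILES writer -----------------------------------------------------------

.default_h_count <- function(elem, charge, bondsum) {
  v <- switch(elem,
    C = if (charge == 0) 4 else 3,
    N = if (charge == 1) 4 else if (charge == -1) 2 else 3,
    O = if (charge == -1) 1 else if (charge == 1) 3 else 2,
    S = if (charge == 0) {
      if (bondsum <= 2) 2 else if (bondsum <= 4) 4 else 6
    } else if (charge == -1) 1 else 3,
    P = if (bondsum <= 3) 3 else 5,
    B = 3,
    F = , Cl = , Br = , I = if (charge == 0) 1 else 0,
    0)
  max(0L, as.integer(v - bondsum))
}

.atom_token <- function(mol, i) {
  elem <- mol$atoms$elem[i]
  charge <- mol$atoms$charge[i]
  if (elem %in% ORGANIC_SUBSET && charge == 0) return(elem)
  h <- .default_h_count(elem, charge, mol_bondsum(mol, i))
  hpart <- if (h == 1) "H" else if (h > 1) paste0("H", h) else ""
  cpart <- if (charge == 0) "" else if (charge == 1) "+" else if (charge == -1) "-"
           else if (charge > 1) paste0("+", charge) else paste0("-", abs(charge))
  paste0("[", elem, hpart, cpart, "]")
}

#' Write a (kekulized) SMILES from a molecular graph
#'
#' Emits uppercase kekulized SMILES with explicit bond orders; aromaticity is
#' re-perceived on canonicalization. Directional bonds are placed around any
#' azo bond listed in \code{stereo} and around pre-existing azo bonds whose
#' geometry was recovered at parse time.
#'
#' @param mol a \code{psw_mol}.
#' @param stereo optional list with elements \code{bond} (length-2 integer:
#'   the azo N indices) and \code{geom} ("E" or "Z").
#' @return a SMILES string.
#' @export
mol_to_smiles <- function(mol, stereo = NULL) {
  n <- mol_n_atoms(mol)
  if (n == 0) return("")
  nb <- nrow(mol$bonds)

  # directional-mark table: bondkey -> list(role, anchor, partner, geom)
  # role "left": single bond c1-n1; role "right": single bond n2-c2.
  dirmarks <- list()
  add_stereo_bond <- function(i, j, geom) {
    ci <- setdiff(mol_neighbors(mol, i), j)
    cj <- setdiff(mol_neighbors(mol, j), i)
    if (length(ci) != 1 || length(cj) != 1) return(invisible(NULL))
    kL <- paste(min(ci, i), max(ci, i), sep = "-")
    kR <- paste(min(j, cj), max(j, cj), sep = "-")
    dirmarks[[kL]] <<- list(role = "left", from = ci, to = i, geom = geom)
    dirmarks[[kR]] <<- list(role = "right", from = j, to = cj, geom = geom)
    invisible(NULL)
  }
  for (key in names(mol$azo_geom)) {
    ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    add_stereo_bond(ij[1], ij[2], mol$azo_geom[[key]])
  }
  if (!is.null(stereo)) add_stereo_bond(stereo$bond[1], stereo$bond[2], stereo$geom)

  bond_symbol <- function(k, u, v) {
    ord <- mol$bonds$order[k]
    if (ord == 2) return("=")
    if (ord == 3) return("#")
    key <- paste(min(u, v), max(u, v), sep = "-")
    dm <- dirmarks[[key]]
    if (is.null(dm)) return("")
    forward <- (u == dm$from)
    if (dm$role == "left") {
      if (forward) "/" else "\\"
    } else {
      up <- dm$geom == "E"
      if (forward == up) "/" else "\\"
    }
  }

  env <- new.env()
  env$visited <- rep(FALSE, n)
  env$bond_used <- rep(FALSE, nb)
  env$closure <- vector("list", n)  # per atom: list of c(digit, bondidx, otheratom)
  env$next_digit <- 1L

  # pass 1: find ring-closure bonds via DFS
  mark <- function(u) {
    env$visited[u] <- TRUE
    for (k in which((mol$bonds$a1 == u | mol$bonds$a2 == u) & !env$bond_used)) {
      v <- if (mol$bonds$a1[k] == u) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (env$visited[v]) {
        env$bond_used[k] <- TRUE
        d <- env$next_digit; env$next_digit <- d + 1L
        env$closure[[u]] <- c(env$closure[[u]], list(list(d = d, k = k, other = v)))
        env$closure[[v]] <- c(env$closure[[v]], list(list(d = d, k = k, other = u)))
      } else {
        env$bond_used[k] <- TRUE
        mark(v)
      }
    }
  }
  # pass 2: emit
  emit <- function(u) {
    tok <- .atom_token(mol, u)
    for (cl in env$closure[[u]]) {
      sym <- bond_symbol(cl$k, u, cl$other)
      dig <- if (cl$d > 9) paste0("%", cl$d) else as.character(cl$d)
      tok <- paste0(tok, sym, dig)
    }
    kids <- list()
    for (k in which((mol$bonds$a1 == u | mol$bonds$a2 == u) & env$tree)) {
      v <- if (mol$bonds$a1[k] == u) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (env$emitted[v]) next
      env$emitted[v] <- TRUE
      kids <- c(kids, list(list(k = k, v = v)))
    }
    parts <- character(0)
    if (length(kids) > 0) {
      for (i in seq_along(kids)) {
        kid <- kids[[i]]
        sub <- paste0(bond_symbol(kid$k, u, kid$v), emit(kid$v))
        parts <- c(parts, if (i < length(kids)) paste0("(", sub, ")") else sub)
      }
    }
    paste0(tok, paste0(parts, collapse = ""))
  }

  out <- character(0)
  comp_roots <- c()
  while (any(!env$visited)) {
    root <- which(!env$visited)[1]
    comp_roots <- c(comp_roots, root)
    mark(root)
  }
  # tree bonds are the used bonds that are not closures
  closure_bonds <- unique(unlist(lapply(env$closure, function(x)
    vapply(x, function(e) e$k, integer(1)))))
  env$tree <- rep(TRUE, nb)
  if (length(closure_bonds)) env$tree[closure_bonds] <- FALSE
  env$emitted <- rep(FALSE, n)
  for (root in comp_roots) {
    env$emitted[root] <- TRUE
    out <- c(out, emit(root))
  }
  paste(out, collapse = ".")
}

#' @export
print.psw_mol <- function(x, ...) {
  cat("<psw_mol>", mol_n_atoms(x), "heavy atoms,", nrow(x$bonds), "bonds;",
      sum(x$atoms$arom), "aromatic atoms\n")
  invisible(x)
}
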