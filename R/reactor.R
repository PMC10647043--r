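# Azologization / azoextension enumeration on the molecular graph.
#
# Each transformation is an explicit graph edit: matching linker atoms are
# deleted and an azo bridge (or phenyldiazene) is installed, with atom
# provenance (parent index) carried through every edit. Raw designs keep the
# edited graph and the identity of the newly created azo bond so that E/Z
# assignment can target exactly that bond even when the parent already
# contains azo groups.

.linker_ok <- function(mol, i, ring_at, elems) {
  !mol$atoms$arom[i] && !ring_at[i] && mol$atoms$elem[i] %in% elems &&
    mol$atoms$elem[i] != "H"
}

.new_raw_design <- function(mol, azo, rule_name, category, site,
                            parent_id, parent_smiles) {
  structure(list(mol = mol, azo = azo, rule_name = rule_name,
                 category = category, site = site,
                 parent_id = parent_id, parent_smiles = parent_smiles),
            class = "psw_raw_design")
}

# install N=N between atoms ca, cb after deleting `del` atoms.
# returns list(mol, azo) or NULL.
.install_azo <- function(mol, ca, cb, del) {
  keep <- setdiff(seq_len(mol_n_atoms(mol)), del)
  ca2 <- match(ca, keep); cb2 <- match(cb, keep)
  m <- mol_delete_atoms(mol, del)
  m <- mol_add_atom(m, "N"); n1 <- mol_n_atoms(m)
  m <- mol_add_atom(m, "N"); n2 <- mol_n_atoms(m)
  m <- mol_add_bond(m, ca2, n1, 1L)
  m <- mol_add_bond(m, n1, n2, 2L)
  m <- mol_add_bond(m, n2, cb2, 1L)
  list(mol = m, azo = c(n1, n2))
}

# append phenyldiazene at aromatic atom `site`, after deleting `del`
.install_phenyldiazene <- function(mol, site, del = integer(0)) {
  keep <- setdiff(seq_len(mol_n_atoms(mol)), del)
  s2 <- match(site, keep)
  m <- mol_delete_atoms(mol, del)
  m <- mol_add_atom(m, "N"); n1 <- mol_n_atoms(m)
  m <- mol_add_atom(m, "N"); n2 <- mol_n_atoms(m)
  ring <- integer(6)
  for (k in 1:6) {
    m <- mol_add_atom(m, "C", arom = TRUE)
    ring[k] <- mol_n_atoms(m)
  }
  m <- mol_add_bond(m, s2, n1, 1L)
  m <- mol_add_bond(m, n1, n2, 2L)
  m <- mol_add_bond(m, n2, ring[1], 1L)
  orders <- c(2L, 1L, 2L, 1L, 2L, 1L)
  for (k in 1:6)
    m <- mol_add_bond(m, ring[k], ring[if (k == 6) 1 else k + 1], orders[k], arom = TRUE)
  list(mol = m, azo = c(n1, n2))
}

# ---- site finders -----------------------------------------------------------

.sites_typical <- function(mol, elems) {
  ring_at <- mol_ring_atoms(mol)
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    x <- mol$bonds$a1[k]; y <- mol$bonds$a2[k]
    if (!.linker_ok(mol, x, ring_at, elems) || !.linker_ok(mol, y, ring_at, elems)) next
    # an N=N linker is already an azo bridge; replacing it is the identity
    if (mol$atoms$elem[x] == "N" && mol$atoms$elem[y] == "N" &&
        mol$bonds$order[k] == 2) next
    nx <- setdiff(mol_neighbors(mol, x), y)
    ny <- setdiff(mol_neighbors(mol, y), x)
    if (length(nx) != 1 || length(ny) != 1) next   # unbranched
    if (!mol$atoms$arom[nx] || !mol$atoms$arom[ny]) next
    out[[length(out) + 1]] <- list(ca = nx, cb = ny, del = c(x, y))
  }
  out
}

.sites_0atom <- function(mol) {
  ring_bd <- mol_ring_bonds(mol)
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    if (isTRUE(ring_bd[k]) || mol$bonds$order[k] != 1) next
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (mol$atoms$arom[a] && mol$atoms$arom[b])
      out[[length(out) + 1]] <- list(ca = a, cb = b, del = integer(0), cut = k)
  }
  out
}

.sites_1atom <- function(mol, elems) {
  ring_at <- mol_ring_atoms(mol)
  out <- list()
  for (x in seq_len(mol_n_atoms(mol))) {
    if (!.linker_ok(mol, x, ring_at, elems)) next
    nb <- mol_neighbors(mol, x)
    ar <- nb[mol$atoms$arom[nb]]
    extra <- setdiff(nb, ar)
    if (length(ar) != 2) next
    if (length(extra) > 1) next
    if (length(extra) == 1 && mol_degree(mol, extra) != 1) next
    out[[length(out) + 1]] <- list(ca = ar[1], cb = ar[2], del = c(x, extra))
  }
  out
}

.sites_3atom <- function(mol, elems) {
  ring_at <- mol_ring_atoms(mol)
  out <- list()
  seen <- character(0)
  lin <- function(i) .linker_ok(mol, i, ring_at, elems)
  for (y in seq_len(mol_n_atoms(mol))) {
    if (!lin(y)) next
    nb_y <- mol_neighbors(mol, y)
    for (x in nb_y) for (z in nb_y) {
      if (x == z || !lin(x) || !lin(z)) next
      for (ca in setdiff(mol_neighbors(mol, x), y)) {
        if (!mol$atoms$arom[ca]) next
        for (cb in setdiff(mol_neighbors(mol, z), y)) {
          if (!mol$atoms$arom[cb] || cb == ca) next
          ok <- TRUE
          branches <- integer(0)
          for (spec in list(c(x, ca, y), c(y, x, z), c(z, y, cb))) {
            extras <- setdiff(mol_neighbors(mol, spec[1]), spec[2:3])
            if (length(extras) > 1 ||
                (length(extras) == 1 && mol_degree(mol, extras) != 1)) { ok <- FALSE; break }
            branches <- c(branches, extras)
          }
          if (!ok) next
          key <- paste(min(ca, cb), max(ca, cb), min(x, z), y, max(x, z))
          if (key %in% seen) next
          seen <- c(seen, key)
          out[[length(out) + 1]] <- list(ca = ca, cb = cb, del = c(x, y, z, branches))
        }
      }
    }
  }
  out
}

# ---- azologization ----------------------------------------------------------

#' Apply azologization rules to a parent ligand
#'
#' Exhaustively matches every azologization site (two-atom linkers for the
#' typical rule; 0-, 1- and 3-atom linkers for the atypical rules) and
#' replaces each linker with an azo bond, producing one design per
#' (rule, site). Naphthalene-type replacement has its own entry point,
#' \code{\link{run_naphthalene_azologization}}, which this function calls
#' when the rule set contains that category.
#'
#' @param parent a SMILES string, or a list/row with \code{ligand_id} and
#'   \code{smiles}.
#' @param rules a \code{\link{build_rule_set}} result.
#' @return a designs data.frame (class \code{psw_designs}); zero rows when
#'   nothing matches.
#' @export
run_azologization <- function(parent, rules = build_rule_set()) {
  p <- .as_parent(parent)
  mol <- mol_from_smiles(p$smiles)
  if (is.null(mol)) stop("parent SMILES does not parse: ", p$smiles)
  elems <- attr(rules, "linker_elements")
  if (is.null(elems)) elems <- c("C", "N", "O", "S")
  raws <- list()
  grab <- function(sites, rule_name, category) {
    for (s in sites) {
      m <- mol
      if (!is.null(s$cut)) m$bonds <- m$bonds[-s$cut, , drop = FALSE]
      ins <- .install_azo(m, s$ca, s$cb, s$del)
      raws[[length(raws) + 1]] <<- .new_raw_design(
        ins$mol, ins$azo, rule_name, category,
        site = paste(sort(c(s$ca, s$cb, s$del)), collapse = "+"),
        p$ligand_id, p$smiles)
    }
  }
  for (i in seq_len(nrow(rules))) {
    cat_i <- rules$category[i]
    if (cat_i == "typical_azologization")
      grab(.sites_typical(mol, elems), rules$name[i], cat_i)
    else if (cat_i == "atypical_azologization") {
      ll <- rules$linker_length[i]
      if (identical(ll, 0)) grab(.sites_0atom(mol), rules$name[i], cat_i)
      if (identical(ll, 1)) grab(.sites_1atom(mol, elems), rules$name[i], cat_i)
      if (identical(ll, 3)) grab(.sites_3atom(mol, elems), rules$name[i], cat_i)
    }
  }
  designs <- .finalize_designs(raws)
  if ("naphthalene_azologization" %in% rules$category) {
    mode <- attr(rules, "naphthalene_mode")
    if (is.null(mode)) mode <- "both"
    designs <- rbind(designs, run_naphthalene_azologization(parent, mode))
  }
  designs
}

# all aromatic 6-cycles (list of integer vectors, ordered around the ring)
.aromatic_6rings <- function(mol) {
  ar <- which(mol$atoms$arom)
  adj <- lapply(seq_len(mol_n_atoms(mol)), function(i)
    intersect(mol_neighbors(mol, i), ar))
  cycles <- list()
  keys <- character(0)
  path <- integer(6)
  dfs <- function(start, u, depth) {
    path[depth] <<- u
    if (depth == 6) {
      if (start %in% adj[[u]]) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% keys)) {
          keys <<- c(keys, key)
          cycles[[length(cycles) + 1]] <<- path
        }
      }
      return(invisible(NULL))
    }
    for (v in adj[[u]]) if (v > start && !(v %in% path[seq_len(depth)])) dfs(start, v, depth + 1)
    invisible(NULL)
  }
  for (s in ar) dfs(s, s, 1)
  cycles
}

# fused 6-6 fully aromatic bicycles whose aromatic component is exactly 10 atoms
.find_naphthalene_cores <- function(mol) {
  rings <- .aromatic_6rings(mol)
  out <- list()
  if (length(rings) < 2) return(out)
  # aromatic connected components
  comp <- rep(NA_integer_, mol_n_atoms(mol))
  cid <- 0
  for (a in which(mol$atoms$arom)) {
    if (!is.na(comp[a])) next
    cid <- cid + 1
    queue <- a; comp[a] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (k in which((mol$bonds$a1 == u | mol$bonds$a2 == u) & mol$bonds$arom)) {
        v <- if (mol$bonds$a1[k] == u) mol$bonds$a2[k] else mol$bonds$a1[k]
        if (is.na(comp[v])) { comp[v] <- cid; queue <- c(queue, v) }
      }
    }
  }
  for (i in seq_along(rings)) for (j in seq_len(i - 1)) {
    shared <- intersect(rings[[i]], rings[[j]])
    if (length(shared) != 2) next
    if (length(mol_bond_between(mol, shared[1], shared[2])) == 0) next
    atoms <- union(rings[[i]], rings[[j]])
    if (length(atoms) != 10) next
    if (sum(comp == comp[atoms[1]], na.rm = TRUE) != 10) next
    out[[length(out) + 1]] <- list(ringA = rings[[i]], ringB = rings[[j]],
                                   fusion = shared, atoms = atoms)
  }
  out
}

# classic naphthalene locants (1-8) for the non-fusion positions; returns,
# for the given substituted atoms, the lexicographically smallest locant set
# over the four symmetry-equivalent numberings.
.naphthalene_locants <- function(mol, core, sub_atoms) {
  path_between <- function(ring, f1, f2) {
    # non-fusion atoms of `ring` ordered from the f1 side to the f2 side
    ord <- ring
    # rotate so that ord starts at f1
    s <- which(ord == f1)
    ord <- c(ord[s:length(ord)], ord[seq_len(s - 1)])
    if (ord[2] == f2) ord <- c(ord[1], rev(ord[-1]))  # go the long way
    ord[2:5]
  }
  best <- NULL
  for (rings in list(list(core$ringA, core$ringB), list(core$ringB, core$ringA))) {
    for (f in list(core$fusion, rev(core$fusion))) {
      pa <- path_between(rings[[1]], f[1], f[2])  # positions 1-4
      pb <- path_between(rings[[2]], f[2], f[1])  # positions 5-8
      locmap <- integer(mol_n_atoms(mol))
      locmap[pa] <- 1:4; locmap[pb] <- 5:8
      loc <- sort(locmap[sub_atoms])
      if (any(loc == 0)) next
      if (is.null(best) || paste(loc, collapse = ",") < paste(best, collapse = ",")) best <- loc
    }
  }
  if (is.null(best)) best <- rep(NA_integer_, length(sub_atoms))
  best
}

#' Naphthalene-type azologization
#'
#' Replaces a mono- or disubstituted fused 6-6 fully aromatic bicycle
#' ("naphthalene-like" ring system) by azobenzene, re-attaching the
#' substituent(s) exhaustively over all azobenzene ring positions. Symmetry
#' duplicates collapse on deduplication: one substituent yields the three
#' distinct ortho/meta/para products, two distinct substituents yield the 19
#' distinct placements of an azobenzene bearing both.
#'
#' @param parent SMILES or list with \code{ligand_id}/\code{smiles}.
#' @param mode "mono", "di" or "both": how many substituents the bicycle must
#'   carry to be transformed.
#' @return a \code{psw_designs} data.frame (deduplicated within this rule
#'   family).
#' @export
run_naphthalene_azologization <- function(parent, mode = c("both", "mono", "di")) {
  mode <- match.arg(mode)
  p <- .as_parent(parent)
  mol <- mol_from_smiles(p$smiles)
  if (is.null(mol)) stop("parent SMILES does not parse: ", p$smiles)
  raws <- list()
  for (core in .find_naphthalene_cores(mol)) {
    subs <- list()
    for (a in setdiff(core$atoms, core$fusion)) {
      for (v in setdiff(mol_neighbors(mol, a), core$atoms)) {
        if (mol$atoms$elem[v] == "H") next
        subs[[length(subs) + 1]] <- c(ring_atom = a, start = v)
      }
    }
    nsub <- length(subs)
    want <- (nsub == 1 && mode %in% c("mono", "both")) ||
            (nsub == 2 && mode %in% c("di", "both"))
    if (!want || nsub == 0 || nsub > 2) next
    loc <- .naphthalene_locants(mol, core, vapply(subs, `[[`, 0L, "ring_atom"))
    keep <- setdiff(seq_len(mol_n_atoms(mol)), core$atoms)
    starts_new <- vapply(subs, function(s) match(s[["start"]], keep), 0L)
    base <- mol_delete_atoms(mol, core$atoms)
    # azobenzene skeleton appended to `base`
    skel <- base
    n0 <- mol_n_atoms(skel)
    for (k in 1:14) skel <- mol_add_atom(skel, if (k %in% c(7, 8)) "N" else "C",
                                         arom = !(k %in% c(7, 8)))
    aA <- n0 + 1:6; n1 <- n0 + 7; n2 <- n0 + 8; aB <- n0 + 9:14
    orders <- c(2L, 1L, 2L, 1L, 2L, 1L)
    for (k in 1:6) {
      skel <- mol_add_bond(skel, aA[k], aA[if (k == 6) 1 else k + 1], orders[k], arom = TRUE)
      skel <- mol_add_bond(skel, aB[k], aB[if (k == 6) 1 else k + 1], orders[k], arom = TRUE)
    }
    skel <- mol_add_bond(skel, aA[1], n1, 1L)
    skel <- mol_add_bond(skel, n1, n2, 2L)
    skel <- mol_add_bond(skel, n2, aB[1], 1L)
    positions <- c(aA[2:6], aB[2:6])
    posname <- c("2", "3", "4", "5", "6", "2p", "3p", "4p", "5p", "6p")
    locname <- paste(loc, collapse = "_")
    if (nsub == 1) {
      for (q in seq_along(positions)) {
        m <- mol_add_bond(skel, starts_new[1], positions[q], 1L)
        raws[[length(raws) + 1]] <- .new_raw_design(
          m, c(n1, n2),
          sprintf("Naphtho_%s_ABz_%s", locname, posname[q]),
          "naphthalene_azologization",
          site = paste(sort(core$atoms), collapse = "+"),
          p$ligand_id, p$smiles)
      }
    } else {
      for (q1 in seq_along(positions)) for (q2 in seq_along(positions)) {
        if (q1 == q2) next
        m <- mol_add_bond(skel, starts_new[1], positions[q1], 1L)
        m <- mol_add_bond(m, starts_new[2], positions[q2], 1L)
        raws[[length(raws) + 1]] <- .new_raw_design(
          m, c(n1, n2),
          sprintf("Naphtho_%s_ABz_%s_%s", locname, posname[q1], posname[q2]),
          "naphthalene_azologization",
          site = paste(sort(core$atoms), collapse = "+"),
          p$ligand_id, p$smiles)
      }
    }
  }
  .finalize_designs(raws)
}

#' Azoextension of a parent ligand
#'
#' Typical azoextension appends a phenyldiazene group (-N=N-C6H5) at every
#' free aromatic C-H position; atypical azoextension replaces a substituent
#' of at most \code{max_replaced_substituent} heavy atoms on an aromatic
#' carbon by phenyldiazene. Enumeration is exhaustive over positions;
#' symmetry-equivalent products collapse on deduplication.
#'
#' @inheritParams run_azologization
#' @param max_replaced_substituent maximum heavy-atom count of a displaced
#'   substituent (atypical rule); overrides the rule-set attribute if given.
#' @return a \code{psw_designs} data.frame.
#' @export
run_azoextension <- function(parent, rules = build_rule_set(),
                             max_replaced_substituent = NULL) {
  p <- .as_parent(parent)
  mol <- mol_from_smiles(p$smiles)
  if (is.null(mol)) stop("parent SMILES does not parse: ", p$smiles)
  if (is.null(max_replaced_substituent)) {
    max_replaced_substituent <- attr(rules, "max_replaced_substituent")
    if (is.null(max_replaced_substituent)) max_replaced_substituent <- 1
  }
  raws <- list()
  if ("typical_azoextension" %in% rules$category) {
    rn <- rules$name[rules$category == "typical_azoextension"][1]
    for (a in seq_len(mol_n_atoms(mol))) {
      if (!mol$atoms$arom[a] || mol$atoms$elem[a] != "C") next
      if (mol_degree(mol, a) != 2 || mol$atoms$charge[a] != 0) next
      ins <- .install_phenyldiazene(mol, a)
      raws[[length(raws) + 1]] <- .new_raw_design(
        ins$mol, ins$azo, rn, "typical_azoextension",
        site = as.character(a), p$ligand_id, p$smiles)
    }
  }
  if ("atypical_azoextension" %in% rules$category) {
    rn <- rules$name[rules$category == "atypical_azoextension"][1]
    for (a in seq_len(mol_n_atoms(mol))) {
      if (!mol$atoms$arom[a] || mol$atoms$elem[a] != "C") next
      nb <- mol_neighbors(mol, a)
      ext <- nb[!mol$atoms$arom[nb] & mol$atoms$elem[nb] != "H"]
      ringnb <- setdiff(nb, ext)
      if (length(ringnb) != 2 || length(ext) != 1) next
      br <- branch_atoms(mol, a, ext)
      if (length(br) > max_replaced_substituent) next
      if (any(mol$atoms$arom[br])) next
      outside <- setdiff(unique(unlist(lapply(br, function(b) mol_neighbors(mol, b)))),
                         c(br, a))
      if (length(outside) > 0) next
      ins <- .install_phenyldiazene(mol, a, del = br)
      raws[[length(raws) + 1]] <- .new_raw_design(
        ins$mol, ins$azo, rn, "atypical_azoextension",
        site = paste(c(a, br), collapse = "+"), p$ligand_id, p$smiles)
    }
  }
  .finalize_designs(raws)
}

# ---- E/Z enumeration and design assembly ------------------------------------

#' Enumerate the trans/cis isomer pair of a design
#'
#' Assigns E (trans) and Z (cis) geometry to the newly created azo bond only;
#' pre-existing azo bonds keep the geometry they had in the parent. Designs
#' whose new azo bond sits in a ring smaller than 9 atoms are rejected
#' (geometry is impossible there).
#'
#' @param design a raw design produced by the run_* enumerators, or a flat
#'   SMILES containing exactly one azo motif.
#' @return named character vector \code{c(trans=, cis=)} of isomeric
#'   canonical SMILES, or \code{NULL} (with a warning) when geometry cannot
#'   be assigned.
#' @export
enumerate_ez_isomers <- function(design) {
  if (is.character(design)) {
    mol <- mol_from_smiles(design)
    if (is.null(mol)) stop("SMILES does not parse: ", design)
    az <- find_azo_motifs(mol)
    if (length(az) != 1)
      stop("expected exactly one azo motif, found ", length(az))
    design <- .new_raw_design(mol, c(az[[1]]["n1"], az[[1]]["n2"]),
                              "adhoc", "adhoc", "", "x", design)
  }
  stopifnot(inherits(design, "psw_raw_design"))
  mol <- design$mol
  rs <- mol_smallest_ring_through(mol, design$azo[1], design$azo[2])
  if (is.finite(rs) && rs < 9) {
    warning("new azo bond lies in a ", rs, "-membered ring; design dropped")
    return(NULL)
  }
  tr <- canonical_smiles(mol_to_smiles(mol, stereo = list(bond = design$azo, geom = "E")))
  ci <- canonical_smiles(mol_to_smiles(mol, stereo = list(bond = design$azo, geom = "Z")))
  if (is.na(tr) || is.na(ci) || tr == ci) {
    warning("could not assign distinct E/Z geometry; design dropped")
    return(NULL)
  }
  c(trans = tr, cis = ci)
}

# assemble a designs data.frame from raw designs, batching canonicalization
.finalize_designs <- function(raws) {
  cols <- c("parent_id", "parent_smiles", "rule_name", "category", "site",
            "product_smiles_raw", "product_smiles_flat", "trans_smiles",
            "cis_smiles", "family_id", "atom_map", "n_heavy_parent",
            "n_heavy_product", "provenance")
  if (length(raws) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$n_heavy_parent <- integer(0); out$n_heavy_product <- integer(0)
    class(out) <- c("psw_designs", "data.frame")
    return(out)
  }
  flat_raw <- vapply(raws, function(r) mol_to_smiles(r$mol), "")
  tr_raw <- vapply(raws, function(r)
    mol_to_smiles(r$mol, stereo = list(bond = r$azo, geom = "E")), "")
  ci_raw <- vapply(raws, function(r)
    mol_to_smiles(r$mol, stereo = list(bond = r$azo, geom = "Z")), "")
  canon <- canonical_smiles(c(flat_raw, tr_raw, ci_raw))
  n <- length(raws)
  flat <- canon[seq_len(n)]; tr <- canon[n + seq_len(n)]; ci <- canon[2 * n + seq_len(n)]

  keep <- logical(n)
  for (i in seq_len(n)) {
    rs <- mol_smallest_ring_through(raws[[i]]$mol, raws[[i]]$azo[1], raws[[i]]$azo[2])
    small_ring <- is.finite(rs) && rs < 9
    keep[i] <- !small_ring && !is.na(flat[i]) && !is.na(tr[i]) && !is.na(ci[i]) &&
      tr[i] != ci[i]
    if (small_ring)
      warning("design ", raws[[i]]$rule_name, "@", raws[[i]]$site,
              ": new azo bond in a ", rs, "-membered ring; dropped", call. = FALSE)
  }
  parent_nha <- new.env()
  rows <- lapply(which(keep), function(i) {
    r <- raws[[i]]
    pm <- r$mol$atoms$parent_idx
    mapped <- which(!is.na(pm))
    pk <- r$parent_smiles
    if (is.null(parent_nha[[pk]])) {
      pmol <- mol_from_smiles(pk)
      parent_nha[[pk]] <- if (is.null(pmol)) NA_integer_ else mol_n_atoms(pmol)
    }
    data.frame(
      parent_id = r$parent_id, parent_smiles = r$parent_smiles,
      rule_name = r$rule_name, category = r$category, site = r$site,
      product_smiles_raw = flat_raw[i], product_smiles_flat = flat[i],
      trans_smiles = tr[i], cis_smiles = ci[i],
      family_id = paste(r$parent_id, r$rule_name, r$site, sep = "|"),
      atom_map = paste(sprintf("%d:%d", pm[mapped], mapped), collapse = ","),
      n_heavy_parent = parent_nha[[pk]],
      n_heavy_product = mol_n_atoms(r$mol),
      provenance = r$rule_name,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("psw_designs", "data.frame")
  out
}

#' Deduplicate designs by canonical flat product
#'
#' Keeps the first occurrence of each distinct constitution (canonical flat
#' product SMILES); the provenance column accumulates every rule/site that
#' reached the product, and merged family ids are recorded. Idempotent.
#'
#' @param designs a \code{psw_designs} data.frame.
#' @return deduplicated \code{psw_designs} with updated \code{provenance} and
#'   \code{merged_family_ids}.
#' @export
deduplicate_designs <- function(designs) {
  if (nrow(designs) == 0) {
    designs$merged_family_ids <- character(0)
    return(designs)
  }
  prov_all <- if ("provenance" %in% names(designs)) designs$provenance else designs$rule_name
  fam_prev <- if ("merged_family_ids" %in% names(designs))
    designs$merged_family_ids else designs$family_id
  sp <- split(seq_len(nrow(designs)), designs$product_smiles_flat)
  first <- sort(vapply(sp, `[[`, 0L, 1))
  out <- designs[first, , drop = FALSE]
  key <- designs$product_smiles_flat[first]
  out$provenance <- vapply(key, function(k) {
    idx <- sp[[k]]
    paste(unique(unlist(strsplit(prov_all[idx], ";", fixed = TRUE))), collapse = ";")
  }, "")
  out$merged_family_ids <- vapply(key, function(k) {
    idx <- sp[[k]]
    paste(unique(unlist(strsplit(fam_prev[idx], ";", fixed = TRUE))), collapse = ";")
  }, "")
  rownames(out) <- NULL
  class(out) <- c("psw_designs", "data.frame")
  out
}

#' Physicochemical descriptors of designs
#'
#' Computes logP, topological polar surface area, molecular weight, fraction
#' of sp3 carbons and heavy-atom count. All are constitution-level, so the
#' trans and cis isomers of a pair share identical values.
#'
#' @param design a \code{psw_designs} data.frame, or a character vector of
#'   SMILES.
#' @return data.frame with columns \code{smiles}, \code{logP}, \code{tpsa},
#'   \code{mw}, \code{fsp3}, \code{nha}.
#' @export
compute_descriptors <- function(design) {
  smiles <- if (is.data.frame(design)) design$product_smiles_flat else design
  rows <- lapply(smiles, function(s) {
    mref <- tryCatch(ChemmineOB::forEachMol("SMILES", paste0(s, "\tm"), identity),
                     error = function(e) NULL)
    if (is.null(mref)) stop("descriptor computation failed: SMILES does not parse: ", s)
    pr <- ChemmineOB::prop_OB(mref)
    mol <- mol_from_smiles(s)
    if (is.null(mol)) stop("descriptor computation failed for ", s)
    is_c <- mol$atoms$elem == "C"
    sp3 <- vapply(which(is_c), function(i) {
      bd <- mol$bonds[mol$bonds$a1 == i | mol$bonds$a2 == i, , drop = FALSE]
      all(bd$order == 1) && !mol$atoms$arom[i]
    }, TRUE)
    data.frame(smiles = s, logP = pr$logP, tpsa = pr$TPSA, mw = pr$MW,
               fsp3 = if (sum(is_c) == 0) 0 else sum(sp3) / sum(is_c),
               nha = mol_n_atoms(mol), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parent-to-product atom correspondence of a design
#'
#' Returns the exact atom mapping tracked through the graph transformation
#' (parent atom index to product atom index in \code{product_smiles_raw}
#' order); atoms of the replaced region are absent from the map.
#'
#' @param design one row of a \code{psw_designs} data.frame.
#' @return data.frame with columns \code{parent_atom}, \code{product_atom}.
#' @export
map_parent_atoms <- function(design) {
  map <- design$atom_map[1]
  if (is.na(map) || !nzchar(map))
    return(data.frame(parent_atom = integer(0), product_atom = integer(0)))
  pairs <- do.call(rbind, strsplit(strsplit(map, ",", fixed = TRUE)[[1]], ":", fixed = TRUE))
  data.frame(parent_atom = as.integer(pairs[, 1]),
             product_atom = as.integer(pairs[, 2]))
}

#' Run the full reactor over a set of parent ligands
#'
#' Applies every azologization and azoextension category present in the rule
#' set to each parent, concatenates and (optionally) deduplicates.
#'
#' @param parents data.frame with columns \code{ligand_id} and \code{smiles}
#'   (a \code{paffinity} column, if present, is carried along), or a
#'   character vector of SMILES.
#' @param rules a \code{psw_rule_set}.
#' @param dedup deduplicate across rules (default TRUE).
#' @return a \code{psw_designs} data.frame.
#' @export
run_reactor <- function(parents, rules = build_rule_set(), dedup = TRUE) {
  if (is.character(parents))
    parents <- data.frame(ligand_id = paste0("P", seq_along(parents)),
                          smiles = parents, stringsAsFactors = FALSE)
  res <- list()
  for (i in seq_len(nrow(parents))) {
    p <- list(ligand_id = parents$ligand_id[i], smiles = parents$smiles[i])
    d1 <- run_azologization(p, rules)
    d2 <- if (any(grepl("azoextension", rules$category)))
      run_azoextension(p, rules) else NULL
    d <- rbind(d1, d2)
    if (dedup && nrow(d) > 0) d <- deduplicate_designs(d)
    if ("paffinity" %in% names(parents))
      d$parent_paffinity <- rep(parents$paffinity[i], nrow(d))
    res[[length(res) + 1]] <- d
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) return(.finalize_designs(list()))
  out <- do.call(rbind, res)
  class(out) <- c("psw_designs", "data.frame")
  out
}

.as_parent <- function(parent) {
  if (is.character(parent)) return(list(ligand_id = "parent", smiles = parent))
  id <- if (!is.null(parent$ligand_id)) parent$ligand_id else "parent"
  sm <- if (!is.null(parent$smiles)) parent$smiles else parent$canonical_smiles
  list(ligand_id = id, smiles = sm)
}

#' Write designs to an SDF file with annotation properties
#'
#' One record per isomer (trans and cis), with parent id, rule name, family
#' id, isomer label and descriptors as SD tags.
#'
#' @param designs a \code{psw_designs} data.frame.
#' @param path output SDF path.
#' @param descriptors include computed descriptors (default TRUE).
#' @return the path, invisibly.
#' @export
write_designs_sdf <- function(designs, path, descriptors = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  desc <- if (descriptors && nrow(designs) > 0) compute_descriptors(designs) else NULL
  for (i in seq_len(nrow(designs))) {
    for (iso in c("trans", "cis")) {
      smi <- if (iso == "trans") designs$trans_smiles[i] else designs$cis_smiles[i]
      sdf <- ob_convert("SMI", "SDF", paste0(smi, "\t", designs$family_id[i], "_", iso, "\n"))
      if (is.null(sdf)) next
      body <- sub("\\$\\$\\$\\$\\s*$", "", sdf)
      tags <- c(parent_id = designs$parent_id[i], rule_name = designs$rule_name[i],
                family_id = designs$family_id[i], isomer = iso,
                smiles = smi)
      if (!is.null(desc))
        tags <- c(tags, logP = desc$logP[i], tpsa = desc$tpsa[i], mw = desc$mw[i],
                  fsp3 = round(desc$fsp3[i], 4), nha = desc$nha[i])
      writeLines(sub("\\n+$", "", body), con)
      for (tn in names(tags))
        writeLines(c(paste0("> <", tn, ">"), as.character(tags[[tn]]), ""), con)
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}
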