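# Molecular connection-table model.
#
# A `molgraph` is a plain list describing one covalent structure:
#   elem    character, element symbol per heavy atom
#   charge  integer, formal charge per atom
#   bonds   integer matrix m x 3 (a1, a2, order) with kekule bond orders
# plus fields derived by finalize_molgraph():
#   degree, nH, ring_atom, ring_bond, arom_atom, arom_bond,
#   sssr (list of atom-index rings), sssr_arom (logical per ring),
#   adj / bond_adj (neighbour and incident-bond lists), valence_ok
#
# Aromaticity model (fixed for all profiles and fingerprints, recorded in
# reports as "sssr-hueckel"): a ring of the smallest set of smallest rings is
# aromatic iff every ring atom can contribute a p orbital and the pi-electron
# count over the ring satisfies 4n+2. Contributions: atom in an endocyclic
# double bond -> 1; exocyclic double bond to N/O/S -> 0; exocyclic double bond
# into a fused ring atom -> 1; exocyclic double bond to a non-ring carbon
# disqualifies the ring; otherwise heteroatoms (N, O, S, P) donate a lone
# pair -> 2; carbanion -> 2; carbocation -> 0; a saturated carbon
# disqualifies the ring. Rings containing triple bonds are never aromatic.

.std_valence <- c(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L, S = 2L,
  Cl = 1L, Br = 1L, I = 1L, Se = 2L
)
.alt_valence <- list(P = c(3L, 5L), S = c(2L, 4L, 6L), Se = c(2L, 4L, 6L))
.atomic_number <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Br = 35L, I = 53L, Se = 34L
)
.organic_elements <- names(.atomic_number)

# Parse one V2000 molblock into a raw molgraph (no derived fields). Explicit
# hydrogens are folded into the heavy-atom H counts.
parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- which(grepl("V2000\\s*$", lines))[1]
  if (is.na(counts)) stop("not a V2000 molblock")
  hdr <- lines[counts]
  n_atoms <- as.integer(substr(hdr, 1, 3))
  n_bonds <- as.integer(substr(hdr, 4, 6))
  at <- lines[(counts + 1):(counts + n_atoms)]
  elem <- trimws(substr(at, 32, 34))
  charge <- integer(n_atoms)
  bonds <- matrix(integer(0), ncol = 3)
  if (n_bonds > 0) {
    bl <- lines[(counts + n_atoms + 1):(counts + n_atoms + n_bonds)]
    bonds <- cbind(
      as.integer(substr(bl, 1, 3)),
      as.integer(substr(bl, 4, 6)),
      as.integer(substr(bl, 7, 9))
    )
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", ln)),
                                  "\\s+")[[1]])
    idx <- fields[seq(1, length(fields), 2)]
    charge[idx] <- fields[seq(2, length(fields), 2)]
  }
  # fold explicit hydrogens into neighbour H counts
  extraH <- integer(n_atoms)
  is_h <- elem == "H"
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- integer(n_atoms)
    remap[keep] <- seq_along(keep)
    if (nrow(bonds) > 0) {
      h_bond <- is_h[bonds[, 1]] | is_h[bonds[, 2]]
      for (b in which(h_bond)) {
        heavy <- if (is_h[bonds[b, 1]]) bonds[b, 2] else bonds[b, 1]
        if (!is_h[heavy]) extraH[heavy] <- extraH[heavy] + 1L
      }
      bonds <- bonds[!h_bond, , drop = FALSE]
      bonds[, 1] <- remap[bonds[, 1]]
      bonds[, 2] <- remap[bonds[, 2]]
    }
    elem <- elem[keep]
    charge <- charge[keep]
    extraH <- extraH[keep]
  }
  list(elem = elem, charge = as.integer(charge),
       bonds = bonds, extraH = extraH)
}

# Implicit hydrogen count for one atom under the standard-valence model.
# Returns NA when no allowed valence accommodates the bond-order sum.
.implicit_h <- function(elem, charge, bond_sum) {
  base <- .std_valence[elem]
  if (is.na(base)) return(NA_integer_)
  allowed <- .alt_valence[[elem]]
  if (is.null(allowed)) allowed <- base
  if (charge > 0 && elem %in% c("N", "P", "O", "S", "Se")) {
    allowed <- allowed + charge
  } else if (charge != 0) {
    allowed <- pmax(allowed - abs(charge), 0L)
  }
  ok <- allowed[allowed >= bond_sum]
  if (length(ok) == 0) return(NA_integer_)
  as.integer(min(ok) - bond_sum)
}

#' Finalize a molecular graph
#'
#' Computes the derived perception fields (implicit hydrogens, ring
#' membership, smallest set of smallest rings, aromaticity) used by the
#' fingerprint engine, scaffold extraction and complexity profiling.
#'
#' @param g a raw molgraph list with `elem`, `charge`, `bonds` and optionally
#'   `extraH` (explicit-hydrogen counts folded in by the molblock parser).
#' @return a `molgraph` object.
#' @keywords internal
finalize_molgraph <- function(g) {
  n <- length(g$elem)
  m <- nrow(g$bonds)
  adj <- vector("list", n)
  bond_adj <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); bond_adj[[i]] <- integer(0) }
  if (m > 0) {
    for (b in seq_len(m)) {
      a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
      bond_adj[[a1]] <- c(bond_adj[[a1]], b)
      bond_adj[[a2]] <- c(bond_adj[[a2]], b)
    }
  }
  degree <- lengths(adj)
  bond_sum <- integer(n)
  if (m > 0) {
    for (b in seq_len(m)) {
      o <- g$bonds[b, 3]
      bond_sum[g$bonds[b, 1]] <- bond_sum[g$bonds[b, 1]] + o
      bond_sum[g$bonds[b, 2]] <- bond_sum[g$bonds[b, 2]] + o
    }
  }
  extraH <- if (is.null(g$extraH)) integer(n) else g$extraH
  nH <- integer(n)
  valence_ok <- TRUE
  for (i in seq_len(n)) {
    h <- .implicit_h(g$elem[i], g$charge[i], bond_sum[i] + extraH[i])
    if (is.na(h)) { valence_ok <- FALSE; h <- 0L }
    nH[i] <- h + extraH[i]
  }
  sssr <- .find_sssr(n, g$bonds, adj, bond_adj)
  ring_bond <- logical(max(m, 0))
  ring_atom <- logical(n)
  for (r in sssr$rings_bonds) ring_bond[r] <- TRUE
  for (r in sssr$rings) ring_atom[r] <- TRUE
  arom <- .perceive_aromaticity(g, sssr, ring_atom, bond_adj)
  structure(
    list(
      elem = g$elem, charge = g$charge, bonds = g$bonds,
      adj = adj, bond_adj = bond_adj, degree = degree, nH = nH,
      ring_atom = ring_atom, ring_bond = ring_bond,
      sssr = sssr$rings, sssr_bonds = sssr$rings_bonds,
      sssr_arom = arom$ring_arom,
      arom_atom = arom$atom, arom_bond = arom$bond,
      valence_ok = valence_ok
    ),
    class = "molgraph"
  )
}

# Smallest set of smallest rings: for every ring bond, the shortest cycle
# through it is found by BFS with that bond removed; candidates are added
# shortest-first until the cyclomatic number of cycles cover all ring bonds.
.find_sssr <- function(n, bonds, adj, bond_adj) {
  m <- nrow(bonds)
  empty <- list(rings = list(), rings_bonds = list())
  if (m == 0) return(empty)
  comp <- .components(n, adj)
  n_rings <- m - n + length(unique(comp))
  if (n_rings <= 0) return(empty)
  bridges <- .bridges(n, bonds, adj, bond_adj)
  ring_bonds <- which(!bridges)
  cand <- list()
  for (b in ring_bonds) {
    path <- .shortest_path(bonds[b, 1], bonds[b, 2], adj, bond_adj, skip = b)
    if (is.null(path)) next
    cand[[length(cand) + 1]] <- list(atoms = path$atoms,
                                     bonds = c(path$bonds, b),
                                     len = length(path$atoms))
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "len"),
               vapply(cand, function(x) paste(sort(x$bonds), collapse = ","),
                      character(1)))
  rings <- list(); rings_bonds <- list()
  covered <- logical(m)
  for (i in ord) {
    rb <- cand[[i]]$bonds
    if (all(covered[rb])) next
    rings[[length(rings) + 1]] <- cand[[i]]$atoms
    rings_bonds[[length(rings_bonds) + 1]] <- rb
    covered[rb] <- TRUE
    if (length(rings) == n_rings) break
  }
  list(rings = rings, rings_bonds = rings_bonds)
}

.components <- function(n, adj) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# Bridge (non-ring bond) detection by DFS low-link.
.bridges <- function(n, bonds, adj, bond_adj) {
  m <- nrow(bonds)
  disc <- integer(n); low <- integer(n)
  bridge <- logical(m)
  timer <- 0L
  # iterative DFS to avoid recursion limits
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, parent_bond = 0L, i = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i <= length(adj[[v]])) {
        w <- adj[[v]][fr$i]
        b <- bond_adj[[v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (b == fr$parent_bond) next
        if (disc[w] == 0L) {
          timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack[[length(stack) + 1]] <- list(v = w, parent_bond = b, i = 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[fr$parent_bond] <- TRUE
        }
      }
    }
  }
  bridge
}

# BFS shortest path between two atoms with one bond removed; returns atom and
# bond sequences, or NULL when disconnected.
.shortest_path <- function(from, to, adj, bond_adj, skip) {
  n <- length(adj)
  prev_atom <- integer(n); prev_bond <- integer(n)
  seen <- logical(n)
  queue <- from; seen[from] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    nb <- adj[[v]]; bb <- bond_adj[[v]]
    for (k in seq_along(nb)) {
      if (bb[k] == skip) next
      w <- nb[k]
      if (!seen[w]) {
        seen[w] <- TRUE
        prev_atom[w] <- v; prev_bond[w] <- bb[k]
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[to]) return(NULL)
  atoms <- to; bonds <- integer(0)
  v <- to
  while (v != from) {
    bonds <- c(bonds, prev_bond[v])
    v <- prev_atom[v]
    atoms <- c(atoms, v)
  }
  list(atoms = atoms, bonds = bonds)
}

.perceive_aromaticity <- function(g, sssr, ring_atom, bond_adj) {
  n <- length(g$elem)
  m <- nrow(g$bonds)
  atom_arom <- logical(n)
  bond_arom <- logical(max(m, 0))
  ring_arom <- logical(length(sssr$rings))
  if (length(sssr$rings) == 0) {
    return(list(atom = atom_arom, bond = bond_arom, ring_arom = ring_arom))
  }
  # per-atom bond orders for quick lookup
  for (ri in seq_along(sssr$rings)) {
    ratoms <- sssr$rings[[ri]]
    rbonds <- sssr$rings_bonds[[ri]]
    if (any(g$bonds[rbonds, 3] == 3L)) next
    pi_e <- 0L
    ok <- TRUE
    for (a in ratoms) {
      dbl <- bond_adj[[a]][g$bonds[bond_adj[[a]], 3] == 2L]
      if (length(dbl) > 0) {
        endo <- any(dbl %in% rbonds)
        if (endo) {
          pi_e <- pi_e + 1L
        } else {
          b <- dbl[1]
          partner <- if (g$bonds[b, 1] == a) g$bonds[b, 2] else g$bonds[b, 1]
          if (ring_atom[partner]) {
            pi_e <- pi_e + 1L          # fused kekule form
          } else if (g$elem[partner] %in% c("N", "O", "S")) {
            pi_e <- pi_e + 0L          # carbonyl-like, contributes nothing
          } else {
            ok <- FALSE; break         # exocyclic C=C kills aromaticity
          }
        }
      } else if (g$elem[a] %in% c("N", "O", "S", "P", "Se")) {
        pi_e <- pi_e + 2L
      } else if (g$elem[a] == "C" && g$charge[a] < 0) {
        pi_e <- pi_e + 2L
      } else if (g$elem[a] == "C" && g$charge[a] > 0) {
        pi_e <- pi_e + 0L
      } else {
        ok <- FALSE; break             # saturated atom in ring
      }
    }
    if (ok && pi_e >= 2L && (pi_e - 2L) %% 4L == 0L) {
      ring_arom[ri] <- TRUE
      atom_arom[ratoms] <- TRUE
      bond_arom[rbonds] <- TRUE
    }
  }
  list(atom = atom_arom, bond = bond_arom, ring_arom = ring_arom)
}

#' Parse a SMILES string into a molecular graph
#'
#' Runs the syntax validator, converts through OpenBabel, and finalizes the
#' connection table (implicit hydrogens, rings, aromaticity). Returns `NULL`
#' for inputs that fail any stage, so callers can treat invalid molecules as
#' data rather than conditions.
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph`, or `NULL` if the SMILES is not a valid single
#'   covalent organic structure.
#' @export
parse_smiles <- function(smiles) {
  if (length(smiles) != 1 || is.na(smiles) || !nzchar(smiles)) return(NULL)
  if (!smiles_syntax_ok(smiles)) return(NULL)
  mb <- .ob_molblocks(smiles)
  if (length(mb) != 1 || is.na(mb)) return(NULL)
  raw <- tryCatch(parse_molblock(mb), error = function(e) NULL)
  if (is.null(raw) || length(raw$elem) == 0) return(NULL)
  if (!all(raw$elem %in% .organic_elements)) return(NULL)
  if (!any(raw$elem == "C")) return(NULL)
  g <- finalize_molgraph(raw)
  if (!g$valence_ok) return(NULL)
  if (length(unique(.components(length(g$elem), g$adj))) != 1) return(NULL)
  g
}

# Write a molgraph as a V2000 molblock (no coordinates; kekule orders).
write_molblock <- function(g, title = "") {
  n <- length(g$elem)
  m <- nrow(g$bonds)
  hdr <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   g$elem)
  lines <- c(title, "  molsearch", "", hdr, atoms)
  if (m > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds[, 1], g$bonds[, 2], g$bonds[, 3]))
  }
  chg <- which(g$charge != 0)
  if (length(chg) > 0) {
    for (i in chg) {
      lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, i, g$charge[i]))
    }
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

# Canonical SMILES of molgraphs through OpenBabel (batched).
molgraph_to_smiles <- function(graphs) {
  if (length(graphs) == 0) return(character(0))
  blocks <- vapply(graphs, write_molblock, character(1))
  .ob_molblock_to_smiles(blocks)
}
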