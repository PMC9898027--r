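# Persistent homology of the super-level-set filtration of a CIF map.
# Dimension 0 is computed by a union-find sweep with the elder rule;
# dimension 1 by boundary-matrix reduction over the cubical complex whose
# top cells are the grid cells (so foreground connectivity is
# 8-connectivity, the complementary 4-connectivity applying to holes).
# Excluded (NA) cells never enter the filtration.

#' Super-level-set filtration of a score grid
#'
#' @param values Numeric matrix of CIF scores; `NA` marks excluded tiles.
#' @return A list of class `cif_filtration` (`values`, `connectivity`).
#' @export
cif_filtration <- function(values) {
  values <- unclass(values)
  attributes(values) <- list(dim = dim(values))
  if (!is.matrix(values)) stop_invalid("values must be a matrix")
  structure(list(values = values, connectivity = 8L),
            class = "cif_filtration")
}

neighbors8 <- function(r, c, nr, nc) {
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rr <- r + dr; cc <- c + dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  cbind(rr[ok], cc[ok])
}

#' Dimension-0 barcode (connected components of the hotspot filtration)
#'
#' Cells are swept in descending score order (ties broken row-major). A
#' component is born at its maximum cell; when two components merge, the
#' younger one (lower birth) dies at the merge value — the elder rule.
#' Components alive after the sweep are open (infinite) bars with `NA`
#' death. Zero-persistence bars are dropped.
#'
#' @param filtration A [cif_filtration()] (a plain matrix is accepted).
#' @return Data frame with `dim`, `birth`, `death` (`NA` = open),
#'   `birth_row`, `birth_col` (1-based grid coordinates of the elder
#'   representative).
#' @export
h0_barcode <- function(filtration) {
  v <- if (inherits(filtration, "cif_filtration")) filtration$values else
    unclass(filtration)
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0) {
    stop("empty-input error: all cells excluded", call. = FALSE)
  }
  rs <- ((idx - 1L) %% nr) + 1L
  cs <- ((idx - 1L) %/% nr) + 1L
  ord <- order(-v[idx], rs, cs)
  parent <- integer(nr * nc)      # 0 = not yet added
  birth <- numeric(nr * nc)
  birth_cell <- integer(nr * nc)
  arrival <- integer(nr * nc)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  bars <- list()
  for (step in seq_along(ord)) {
    k <- ord[step]
    lin <- idx[k]; r <- rs[k]; c <- cs[k]
    val <- v[lin]
    parent[lin] <- lin
    birth[lin] <- val
    birth_cell[lin] <- lin
    arrival[lin] <- step
    nb <- neighbors8(r, c, nr, nc)
    nlin <- (nb[, 2] - 1L) * nr + nb[, 1]
    nlin <- nlin[parent[nlin] != 0L]
    for (m in nlin) {
      ra <- find(lin); rb <- find(m)
      if (ra == rb) next
      # elder rule: survivor has the higher birth; ties to earlier arrival
      if (birth[ra] > birth[rb] ||
          (birth[ra] == birth[rb] && arrival[ra] < arrival[rb])) {
        elder <- ra; young <- rb
      } else {
        elder <- rb; young <- ra
      }
      if (birth[young] > val) {
        bars[[length(bars) + 1L]] <-
          c(birth[young], val, birth_cell[young])
      }
      parent[young] <- elder
    }
  }
  roots <- unique(vapply(idx, function(l) find(l), integer(1)))
  open_bars <- lapply(roots, function(rt) c(birth[rt], NA_real_,
                                            birth_cell[rt]))
  all_bars <- c(bars, open_bars)
  bc <- vapply(all_bars, function(b) b[3], numeric(1))
  data.frame(dim = 0L,
             birth = vapply(all_bars, function(b) b[1], numeric(1)),
             death = vapply(all_bars, function(b) b[2], numeric(1)),
             birth_row = ((bc - 1) %% nr) + 1,
             birth_col = ((bc - 1) %/% nr) + 1)
}

# Cubical complex of the super-level filtration: grid cells are squares
# (2-cells); edges and vertices enter with the maximum over their incident
# present squares. Returns the sorted cell table and boundary structure.
build_cubical <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- ifelse(is.na(v), -Inf, v)
  # vertices (i,j), i in 0..nr, j in 0..nc: max over 4 surrounding squares
  vert <- pmax(pad[1:(nr + 1), 1:(nc + 1)], pad[1:(nr + 1), 2:(nc + 2)],
               pad[2:(nr + 2), 1:(nc + 1)], pad[2:(nr + 2), 2:(nc + 2)])
  # horizontal edges (i,j), i in 0..nr, j in 0..nc-1: squares above/below
  he <- pmax(pad[1:(nr + 1), 2:(nc + 1)], pad[2:(nr + 2), 2:(nc + 1)])
  # vertical edges (i,j), i in 0..nr-1, j in 0..nc: squares left/right
  ve <- pmax(pad[2:(nr + 1), 1:(nc + 1)], pad[2:(nr + 1), 2:(nc + 2)])
  sq <- ifelse(is.na(v), -Inf, v)

  # cell tables: type 0 vertex, 1 h-edge, 2 v-edge, 3 square
  cell_type <- c(rep(0L, length(vert)), rep(1L, length(he)),
                 rep(2L, length(ve)), rep(3L, length(sq)))
  cell_val <- c(as.vector(t(vert)), as.vector(t(he)), as.vector(t(ve)),
                as.vector(t(sq)))  # row-major ids within each type
  n_vert <- length(vert); n_he <- length(he); n_ve <- length(ve)
  present <- is.finite(cell_val)
  # sorted position: descending value; ties vertices < edges < squares,
  # then row-major id
  dim_rank <- c(0L, 1L, 1L, 2L)[cell_type + 1L]
  ordc <- order(-cell_val, dim_rank, cell_type, seq_along(cell_val))
  ordc <- ordc[present[ordc]]
  pos <- integer(length(cell_val))
  pos[ordc] <- seq_along(ordc)
  list(nr = nr, nc = nc, n_vert = n_vert, n_he = n_he, n_ve = n_ve,
       cell_type = cell_type, cell_val = cell_val, present = present,
       order = ordc, pos = pos)
}

# Global cell ids (row-major within type, offset by type)
cub_vid <- function(cx, i, j) i * (cx$nc + 1) + j + 1L
cub_hid <- function(cx, i, j) cx$n_vert + i * cx$nc + j + 1L
cub_veid <- function(cx, i, j) cx$n_vert + cx$n_he + i * (cx$nc + 1) + j + 1L
cub_sid <- function(cx, i, j) cx$n_vert + cx$n_he + cx$n_ve + i * cx$nc + j + 1L

#' Dimension-1 barcode (holes of the hotspot filtration)
#'
#' Persistent homology in dimension 1 of the super-level cubical
#' filtration, by boundary-matrix reduction over Z/2. A hole is born when a
#' cycle of present cells encloses absent cells and dies when the enclosed
#' cells enter. Holes around permanently excluded (`NA`) cells never die;
#' they are open bars, dropped by default and counted as `mask_holes`.
#'
#' @param filtration A [cif_filtration()] (or plain matrix).
#' @param keep_open Keep open dimension-1 bars (death `NA`) in the output.
#' @return Data frame with `dim`, `birth`, `death`, `birth_row`,
#'   `birth_col` (all `NA` for grid coordinates, which are only tracked for
#'   dimension 0), and attribute `mask_holes`.
#' @export
h1_barcode <- function(filtration, keep_open = FALSE) {
  v <- if (inherits(filtration, "cif_filtration")) filtration$values else
    unclass(filtration)
  if (all(is.na(v))) stop("empty-input error: all cells excluded",
                          call. = FALSE)
  cx <- build_cubical(v)
  nr <- cx$nr; nc <- cx$nc
  ncells <- length(cx$order)
  cols <- vector("list", ncells)
  pivot_owner <- integer(ncells)      # sorted position -> column position
  edge_positive <- logical(ncells)
  pairs_birth <- numeric(0); pairs_death <- numeric(0)

  boundary_of <- function(cid) {
    ct <- cx$cell_type[cid]
    if (ct == 0L) return(integer(0))
    local_id <- if (ct == 1L) cid - cx$n_vert
    else if (ct == 2L) cid - cx$n_vert - cx$n_he
    else cid - cx$n_vert - cx$n_he - cx$n_ve
    if (ct == 1L) {            # h-edge (i,j): vertices (i,j), (i,j+1)
      i <- (local_id - 1L) %/% nc; j <- (local_id - 1L) %% nc
      b <- c(cub_vid(cx, i, j), cub_vid(cx, i, j + 1L))
    } else if (ct == 2L) {     # v-edge (i,j): vertices (i,j), (i+1,j)
      i <- (local_id - 1L) %/% (nc + 1L); j <- (local_id - 1L) %% (nc + 1L)
      b <- c(cub_vid(cx, i, j), cub_vid(cx, i + 1L, j))
    } else {                   # square (i,j): its 4 edges
      i <- (local_id - 1L) %/% nc; j <- (local_id - 1L) %% nc
      b <- c(cub_hid(cx, i, j), cub_hid(cx, i + 1L, j),
             cub_veid(cx, i, j), cub_veid(cx, i, j + 1L))
    }
    sort(cx$pos[b])
  }

  for (p in seq_len(ncells)) {
    cid <- cx$order[p]
    ct <- cx$cell_type[cid]
    if (ct == 0L) next
    B <- boundary_of(cid)
    repeat {
      if (length(B) == 0) break
      low <- B[length(B)]
      owner <- pivot_owner[low]
      if (owner == 0L) break
      other <- cols[[owner]]
      B <- sort(c(setdiff(B, other), setdiff(other, B)))
    }
    if (length(B) == 0) {
      if (ct %in% c(1L, 2L)) edge_positive[p] <- TRUE
    } else {
      low <- B[length(B)]
      pivot_owner[low] <- p
      cols[[p]] <- B
      if (ct == 3L) {
        low_cid <- cx$order[low]
        # pivot of a square is a positive edge: an H1 pair
        pairs_birth <- c(pairs_birth, cx$cell_val[low_cid])
        pairs_death <- c(pairs_death, cx$cell_val[cid])
        edge_positive[low] <- FALSE   # paired, not open
      }
    }
  }
  keep <- pairs_birth > pairs_death
  birth <- pairs_birth[keep]; death <- pairs_death[keep]
  n_open <- sum(edge_positive)
  if (keep_open && n_open > 0) {
    open_births <- cx$cell_val[cx$order[which(edge_positive)]]
    birth <- c(birth, open_births)
    death <- c(death, rep(NA_real_, n_open))
  }
  out <- data.frame(dim = rep(1L, length(birth)), birth = birth,
                    death = death,
                    birth_row = rep(NA_real_, length(birth)),
                    birth_col = rep(NA_real_, length(birth)))
  attr(out, "mask_holes") <- n_open
  out
}

#' Full barcode of a CIF map
#'
#' @param map Matrix of scores (`NA` = excluded), or a [cif_filtration()].
#' @param keep_open_h1 Keep open dimension-1 bars; see [h1_barcode()].
#' @return Data frame of class `cif_barcode` with dimensions 0 and 1 and
#'   attribute `mask_holes`.
#' @export
compute_barcode <- function(map, keep_open_h1 = FALSE) {
  filt <- if (inherits(map, "cif_filtration")) map else cif_filtration(map)
  b0 <- h0_barcode(filt)
  b1 <- h1_barcode(filt, keep_open = keep_open_h1)
  out <- rbind(b0, b1)
  attr(out, "mask_holes") <- attr(b1, "mask_holes")
  class(out) <- c("cif_barcode", "data.frame")
  out
}

# Number of bars of dimension d alive at threshold t: born at or above t
# and not yet dead (open bars never die).
bars_alive <- function(barcode, t, dim = 0L) {
  b <- barcode[barcode$dim == dim, , drop = FALSE]
  sum(b$birth >= t & (is.na(b$death) | b$death < t))
}

#' Brute-force super-level-set oracle
#'
#' For every distinct score, explicitly builds the super-level set and
#' counts 8-connected components by flood fill and independent cycles by
#' the Euler characteristic of the cell closure
#' (`cycles = components - vertices + edges - faces`). Test oracle only;
#' guarded to small grids.
#'
#' @param filtration A [cif_filtration()] or matrix.
#' @return Data frame with `threshold`, `n_components`, `n_cycles`.
#' @export
brute_force_oracle <- function(filtration) {
  v <- if (inherits(filtration, "cif_filtration")) filtration$values else
    unclass(filtration)
  nr <- nrow(v); nc <- ncol(v)
  if (nr > 32 || nc > 32) {
    stop("guard error: oracle restricted to grids of at most 32x32",
         call. = FALSE)
  }
  vals <- sort(unique(v[!is.na(v)]), decreasing = TRUE)
  if (length(vals) == 0) stop("empty-input error: all cells excluded",
                              call. = FALSE)
  res <- lapply(vals, function(t) {
    mask <- !is.na(v) & v >= t
    # flood-fill component count, 8-connectivity
    seen <- matrix(FALSE, nr, nc)
    ncomp <- 0L
    for (lin in which(mask)) {
      r0 <- ((lin - 1L) %% nr) + 1L; c0 <- ((lin - 1L) %/% nr) + 1L
      if (seen[r0, c0]) next
      ncomp <- ncomp + 1L
      queue <- lin; seen[lin] <- TRUE
      while (length(queue) > 0) {
        cur <- queue[1]; queue <- queue[-1]
        r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
        nb <- neighbors8(r, c, nr, nc)
        nlin <- (nb[, 2] - 1L) * nr + nb[, 1]
        nlin <- nlin[mask[nlin] & !seen[nlin]]
        seen[nlin] <- TRUE
        queue <- c(queue, nlin)
      }
    }
    # closure cell counts of the T-construction
    pm <- matrix(FALSE, nr + 2, nc + 2)
    pm[2:(nr + 1), 2:(nc + 1)] <- mask
    vpres <- pm[1:(nr + 1), 1:(nc + 1)] | pm[1:(nr + 1), 2:(nc + 2)] |
      pm[2:(nr + 2), 1:(nc + 1)] | pm[2:(nr + 2), 2:(nc + 2)]
    hpres <- pm[1:(nr + 1), 2:(nc + 1)] | pm[2:(nr + 2), 2:(nc + 1)]
    vepres <- pm[2:(nr + 1), 1:(nc + 1)] | pm[2:(nr + 1), 2:(nc + 2)]
    nV <- sum(vpres); nE <- sum(hpres) + sum(vepres); nF <- sum(mask)
    c(threshold = t, n_components = ncomp,
      n_cycles = ncomp - nV + nE - nF)
  })
  as.data.frame(do.call(rbind, res))
}

#' Topological feature vector of a barcode
#'
#' Deterministic scalar statistics of the dimension 0 and 1 bars. Open
#' bars contribute to counts and births but are excluded from persistence
#' statistics unless a `death_floor` (e.g. the global score minimum) is
#' supplied. Two hotspot counters are provided: `n_hotspots_above` counts
#' dimension-0 bars born at or above an absolute score threshold, and
#' `n_persistent_dim0` counts finite dimension-0 bars whose persistence
#' reaches `min_persistence` — the latter is invariant to sample-wide score
#' shifts.
#'
#' @param barcode A `cif_barcode` (or data frame with `dim`, `birth`,
#'   `death`).
#' @param hotspot_threshold Absolute birth threshold for
#'   `n_hotspots_above`.
#' @param min_persistence Persistence threshold for `n_persistent_dim0`.
#' @param death_floor Optional death value substituted for open bars.
#' @return Named numeric vector.
#' @export
barcode_features <- function(barcode, hotspot_threshold = 0.6,
                             min_persistence = 0.15, death_floor = NULL) {
  per_dim <- function(d) {
    b <- barcode[barcode$dim == d, , drop = FALSE]
    death <- b$death
    if (!is.null(death_floor)) death[is.na(death)] <- death_floor
    fin <- !is.na(death)
    pers <- b$birth[fin] - death[fin]
    ent <- if (length(pers) >= 2 && sum(pers) > 0) {
      p <- pers / sum(pers); p <- p[p > 0]
      -sum(p * log(p))
    } else 0
    list(n = nrow(b),
         total = if (length(pers)) sum(pers) else 0,
         mx = if (length(pers)) max(pers) else 0,
         mean_birth = if (nrow(b)) mean(b$birth) else 0,
         entropy = ent,
         pers = pers,
         births = b$birth)
  }
  d0 <- per_dim(0L); d1 <- per_dim(1L)
  c(n_bars_dim0 = d0$n, n_bars_dim1 = d1$n,
    total_persistence_dim0 = d0$total, total_persistence_dim1 = d1$total,
    max_persistence_dim0 = d0$mx, max_persistence_dim1 = d1$mx,
    mean_birth_dim0 = d0$mean_birth, mean_birth_dim1 = d1$mean_birth,
    n_hotspots_above = sum(d0$births >= hotspot_threshold),
    n_persistent_dim0 = sum(d0$pers >= min_persistence),
    persistence_entropy_dim0 = d0$entropy,
    persistence_entropy_dim1 = d1$entropy)
}
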