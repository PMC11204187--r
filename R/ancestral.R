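## Most-parsimonious ancestral-state reconstruction.
##
## Per character the engine runs a unit-cost dynamic program (Sankoff with
## 0/1 costs) over the display-rooted tree: down[v,s] is the optimal cost of
## v's subtree given state s at v, up[v,s] the optimal cost of the rest of the
## tree. Their sum identifies the MPR set (states attainable at v in at least
## one most-parsimonious reconstruction), and greedy top-down backtracking
## with a state preference yields the ACCTRAN and DELTRAN assignments. The
## display root sits on the pendant edge of the chosen root taxon; internally
## the root taxon is tip 1 of the traversal encoding.

INF <- 1e9

ptree_depths <- function(pt) {
  depth <- integer(length(pt$parent))
  for (v in seq_along(pt$parent)) {
    d <- 0L; u <- v
    while (pt$parent[u] > 0L) { u <- pt$parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  depth
}

# allowed state values per tip for character j (missing = all observed)
allowed_states <- function(matrix, tip_order, j) {
  col <- matrix$states[match(tip_order, matrix$taxa), j]
  obs <- sort(unique(col[!is.na(col)]))
  if (!length(obs)) obs <- 0L
  lapply(col, function(x) if (is.na(x)) obs else x)
}

# full up/down DP for one character on a ptree; S = candidate state values
dp_one_char <- function(pt, allowed) {
  n <- pt$ntip
  S <- sort(unique(unlist(allowed)))
  K <- length(S)
  nn <- length(pt$parent)
  ch <- ptree_children(pt)
  depth <- ptree_depths(pt)
  internals <- which(seq_len(nn) > n)
  post <- internals[order(depth[internals], decreasing = TRUE)]
  down <- matrix(INF, nn, K)
  for (t in seq_len(n)) down[t, match(allowed[[t]], S)] <- 0
  contrib <- function(v) pmin(down[v, ], min(down[v, ]) + 1)
  for (v in post) {
    acc <- numeric(K)
    for (c in ch[[v]]) acc <- acc + contrib(c)
    down[v, ] <- acc
  }
  rc <- ch[[1]][1]
  root_edge_cost <- ifelse(S %in% allowed[[1]], 0, 1)
  L <- min(down[rc, ] + root_edge_cost)
  up <- matrix(INF, nn, K)
  up[rc, ] <- root_edge_cost
  up[1, ] <- contrib(rc)          # rest-of-tree seen from the root taxon leaf
  pre <- internals[order(depth[internals])]
  for (p in pre) {
    kids <- ch[[p]]
    for (v in kids) {
      sib <- setdiff(kids, v)
      inner <- up[p, ]
      for (b in sib) inner <- inner + contrib(b)
      up[v, ] <- pmin(inner, min(inner) + 1)
    }
  }
  list(S = S, K = K, L = L, down = down, up = up, ch = ch, post = post,
       pre = pre, rc = rc, n = n, allowed = allowed)
}

# MPR state sets per node (including tips, where they collapse to the data)
dp_mpr_sets <- function(dp) {
  nn <- nrow(dp$down)
  lapply(seq_len(nn), function(v) {
    if (all(dp$down[v, ] >= INF) && all(dp$up[v, ] >= INF)) return(integer(0))
    tot <- dp$down[v, ] + dp$up[v, ]
    dp$S[tot == dp$L]
  })
}

# ACCTRAN: classic Fitch downpass state sets resolved root-to-tips, keeping
# the parent state whenever the downpass set allows it (reversals over
# parallelisms; changes pulled toward the root).
acctran_assign <- function(pt, allowed) {
  n <- pt$ntip
  nn <- length(pt$parent)
  ch <- ptree_children(pt)
  depth <- ptree_depths(pt)
  internals <- which(seq_len(nn) > n)
  post <- internals[order(depth[internals], decreasing = TRUE)]
  D <- vector("list", nn)
  for (t in seq_len(n)) D[[t]] <- allowed[[t]]
  for (v in post) {
    a <- D[[ch[[v]][1]]]; b <- D[[ch[[v]][2]]]
    i <- intersect(a, b)
    D[[v]] <- if (length(i)) i else sort(union(a, b))
  }
  rc <- ch[[1]][1]
  state <- integer(nn)
  i <- intersect(allowed[[1]], D[[rc]])
  state[1] <- if (length(i)) min(i) else min(allowed[[1]])
  pre <- c(rc, internals[order(depth[internals])], seq_len(n)[-1])
  pre <- pre[!duplicated(pre)]
  for (v in pre) {
    sp <- state[pt$parent[v]]
    state[v] <- if (sp %in% D[[v]]) sp else min(D[[v]])
  }
  state
}

# DELTRAN: top-down backtracking of the DP, keeping the parent state whenever
# it is among the optimal continuations (changes pushed toward the tips).
deltran_assign <- function(pt, dp) {
  n <- pt$ntip
  nn <- length(pt$parent)
  state <- integer(nn)
  rc <- dp$rc
  # root taxon leaf first: any allowed state compatible with the optimum
  cands <- dp$S[dp$S %in% dp$allowed[[1]]]
  costs <- vapply(cands, function(t) {
    min(dp$down[rc, ] + ifelse(dp$S == t, 0, 1))
  }, 0)
  state[1] <- cands[which(costs == dp$L)[1]]
  depth <- ptree_depths(pt)
  internals <- which(seq_len(nn) > n)
  pre <- c(rc, internals[order(depth[internals])], seq_len(n)[-1])
  pre <- pre[!duplicated(pre)]
  for (v in pre) {
    sp <- state[pt$parent[v]]
    opt <- dp$down[v, ] + ifelse(dp$S == sp, 0, 1)
    best <- dp$S[opt == min(opt)]
    state[v] <- if (sp %in% best) sp else min(best)
  }
  state
}

assignment_changes <- function(pt, state) {
  kids <- which(pt$parent > 0)
  chg <- kids[state[kids] != state[pt$parent[kids]]]
  data.frame(node = chg, from = state[pt$parent[chg]], to = state[chg])
}

# For every edge (parent(v), v): can a change be placed there in at least one
# MPR, must one be placed there in every MPR, and which derived states occur.
edge_change_profile <- function(pt, dp) {
  n <- pt$ntip
  nn <- length(pt$parent)
  S <- dp$S
  contrib <- function(v) pmin(dp$down[v, ], min(dp$down[v, ]) + 1)
  out <- vector("list", nn)
  for (v in seq_len(nn)[-1]) {
    p <- pt$parent[v]
    if (p == 0) next
    p_side <- if (p == 1L) {
      ifelse(S %in% dp$allowed[[1]], 0, INF)          # root taxon leaf
    } else {
      dp$up[p, ] + dp$down[p, ] - contrib(v)          # rest of tree given p's state
    }
    tot <- outer(p_side, dp$down[v, ], "+")           # [s_p, t_v] without edge cost
    same <- min(diag(tot))
    diffmat <- tot + ifelse(outer(S, S, "!="), 1, INF * (outer(S, S, "==")))
    can <- diffmat <= dp$L
    out[[v]] <- list(
      can_change = any(can),
      forced = same > dp$L,
      derived = sort(unique(S[col(can)[can]])))
  }
  out
}
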