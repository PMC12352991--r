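# Shared fixture builders and independent oracles.

# Apex records realising a vector of group statuses ("closed"/"open"/
# "unknown") on the default ladder. Unknown groups are simply omitted.
records_from_status <- function(status, ladder = becker_ladder()) {
  groups <- ladder[!ladder$excluded, ]
  rows <- lapply(seq_along(status), function(g) {
    if (status[g] == "unknown") return(NULL)
    teeth <- groups$tooth_fdi[groups$group == g]
    tibble::tibble(tooth_fdi = teeth, apex_status = status[g])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble::tibble(tooth_fdi = character(), apex_status = character())
  out
}

closed_records <- function(teeth) tibble::tibble(tooth_fdi = teeth, apex_status = "closed")
open_records <- function(teeth) tibble::tibble(tooth_fdi = teeth, apex_status = "open")

# assessed groups of the default ladder, one row per rung in walk order
ladder_groups_tbl <- function(ladder = becker_ladder()) {
  g <- ladder[!ladder$excluded, ]
  g <- unique(g[, c("group", "da_low", "da_high")])
  g[order(g$group), ]
}

# teeth of groups 1..k / of groups above k on a ladder
ladder_teeth_upto <- function(k, ladder = becker_ladder()) {
  ladder$tooth_fdi[!is.na(ladder$group) & ladder$group <= k]
}
ladder_teeth_above <- function(k, ladder = becker_ladder()) {
  ladder$tooth_fdi[!ladder$excluded & !is.na(ladder$group) & ladder$group > k]
}

# Independent "longest closed prefix" oracle: a deliberately naive loop,
# structured differently from the package's walk.
oracle_walk <- function(status) {
  k <- 0L
  for (g in seq_along(status)) {
    if (status[g] == "open") break
    if (status[g] == "closed") k <- g
  }
  first_open <- Inf
  for (g in seq_along(status)) {
    if (status[g] == "open") { first_open <- g; break }
  }
  inconsistent <- FALSE
  if (is.finite(first_open)) {
    for (g in seq_along(status)) {
      if (g > first_open && status[g] == "closed") inconsistent <- TRUE
    }
  }
  list(
    k = k,
    incomplete = any(status == "unknown"),
    inconsistent = inconsistent
  )
}

# every status vector over {closed, open, unknown}^n
all_status_vectors <- function(n) {
  grid <- expand.grid(rep(list(c("closed", "open", "unknown")), n),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

# Brute-force signed-rank oracle: enumerate all 2^n sign assignments of the
# ranked |d| and count tail mass directly. Usable up to n ~ 15.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_lower <- mean(w_all <= w_obs + 1e-9)
  p_upper <- mean(w_all >= w_obs - 1e-9)
  list(w = w_obs, p = min(1, 2 * min(p_lower, p_upper)))
}

# From-scratch two-way ANOVA mean squares for the ICC oracle.
oracle_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_rows <- k * sum((rowMeans(mat) - grand)^2)
  ss_cols <- n * sum((colMeans(mat) - grand)^2)
  ss_err <- sum((mat - grand)^2) - ss_rows - ss_cols
  list(
    bms = ss_rows / (n - 1),
    jms = ss_cols / (k - 1),
    ems = ss_err / ((n - 1) * (k - 1)),
    wms = (ss_cols + ss_err) / (n * (k - 1)),
    n = n, k = k
  )
}

# long ratings tibble from a subjects x raters matrix
ratings_long <- function(mat) {
  tibble::tibble(
    subject_id = rep(seq_len(nrow(mat)), ncol(mat)),
    rater_id = rep(paste0("R", seq_len(ncol(mat))), each = nrow(mat)),
    da_point = as.vector(mat)
  )
}
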