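# shared fixtures and independent oracles

tiny_schema <- function() {
  dataset_schema(list(gender = c("Male", "Female"),
                      age = c("young", "old")))
}

tiny_temporal_schema <- function(T_len = 5) {
  dataset_schema(
    protected_attrs = list(gender = c("Male", "Female")),
    temporal_features = list(hr = sprintf("hr_%d", seq_len(T_len)))
  )
}

tiny_table <- function(n_each = 2) {
  expand.grid(gender = c("Male", "Female"), age = c("young", "old"),
              stringsAsFactors = FALSE)[rep(1:4, each = n_each), ]
}

# identity pair: synthetic is an exact copy of the real table
identity_pair <- function(df, schema) {
  dataset_pair(as_tabular_dataset(df, schema, "real"),
               as_tabular_dataset(df, schema, "synthetic"),
               schema)
}

# exhaustive hypergeometric enumeration: two-sided Fisher p-value by
# summing probabilities of all 2x2 tables with the observed margins that
# are at most as probable as the observed table
fisher_oracle <- function(count_S, n_S, count_R, n_R) {
  m1 <- count_S + count_R
  xs <- max(0, m1 - n_R):min(m1, n_S)
  probs <- choose(n_S, xs) * choose(n_R, m1 - xs) / choose(n_S + n_R, m1)
  p_obs <- choose(n_S, count_S) * choose(n_R, count_R) /
    choose(n_S + n_R, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand step-up adjustment: sort ascending, scale p(i) by m/i, enforce
# monotonicity from the largest down, cap at 1, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# mapped Pearson correlation from explicit population moments
pcc_oracle <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  r <- mean(ca * cb) / (sqrt(mean(ca^2)) * sqrt(mean(cb^2)))
  (r + 1) / 2
}

# which joint-distribution cells belong to a subgroup
cell_membership <- function(joint, sg, schema) {
  mask <- rep(TRUE, nrow(joint))
  for (attr in names(sg$assignment)) {
    mask <- mask & (joint[[attr]] == sg$assignment[[attr]])
  }
  mask
}

# brute-force lattice enumeration by generate-and-dedupe over all
# level assignments (attributes may also be unassigned)
lattice_oracle <- function(schema) {
  choices <- lapply(schema$protected_attrs, function(lv) c(NA, lv))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  labs <- apply(grid, 1, function(row) {
    keep <- !is.na(row)
    if (!any(keep)) return(NA_character_)
    paste(sprintf("%s=%s", names(row)[keep], row[keep]), collapse = "&")
  })
  unique(labs[!is.na(labs)])
}
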