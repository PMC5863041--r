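# Shared small simulation fixtures, built once per test file.

tiny_params <- function(seed = 42L, ...) {
  sim_params(n_sites_per_class = 5L, fragments_per_site = 200L,
             seed = seed, ...)
}

tiny_panel <- function(seed = 42L, ...) {
  build_site_panel(tiny_params(seed = seed, ...))
}

# Ground-truth class per anchor, with the two co-bound subclasses merged
# (they are identical in ChIP fragment-length composition).
merged_truth <- function(panel, ids) {
  cls <- panel$sites$class_label[match(ids, panel$sites$site_id)]
  ifelse(cls %in% c("C4a", "C4b"), "C4", cls)
}

# A one-site panel of the requested class (other sites removed).
single_site_panel <- function(class_label, params) {
  panel <- build_site_panel(params)
  panel$sites <- panel$sites[panel$sites$class_label == class_label, ][1, ]
  panel
}
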