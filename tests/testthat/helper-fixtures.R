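# Frozen fixture values, computed once from independent oracle runs on the
# default study conditions.

# component-mean abundance RMSE on the default noisy phantom
# (noise_sd = 0.02, seed = 17, lambda = 0.01): exact active-set oracle gives
# 0.02571; threshold = 1.05 x oracle value.
FIX_NOISY_RMSE_THRESHOLD <- 0.0270

# minimum mean SSIM of the 5-channel result against the 45-channel result
# over phantom seeds 1..10 was 0.7503; threshold = floor(0.95 x min, 2 dp).
FIX_SSIM_K5_THRESHOLD <- 0.71

# exact condition number of the default 5 x 45 reference matrix, computed
# once from its singular values.
FIX_DEFAULT_LIBRARY_KAPPA <- 21.65997
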