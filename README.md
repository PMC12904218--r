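# cidereverb

Reverberation is one of the most damaging everyday interferers for
cochlear implant (CI) users: CI processors transmit slow temporal
envelopes and discard fine structure, and reverberant tails fill the
gaps between syllables, flattening exactly those envelopes.
`cidereverb` is an R toolkit for studying that problem in simulation,
end to end:

* **Room acoustics** — a seeded image-source simulator for shoebox rooms
  with a spherical-head receiver, Eyring-based inversion of the surface
  reflection coefficient from a target RT60, Schroeder (T30) RT60
  estimation, and direct-to-reverberant ratio (DRR) metrics.
* **Dereverberation** — single-channel weighted prediction error (WPE)
  filtering in the STFT domain: per frequency bin the reverberant tail is
  modelled autoregressively and subtracted as the predictable part,
  `d_t = x_t - sum_l g_l x_{t-delay-l+1}`, with the taps solving least
  squares weighted by the inverse desired-speech PSD (oracle or
  iterative). An optional late-reverberation Wiener post-filter (the
  "WPEPF" variant) suppresses the residual tail with an
  exponential-decay late-power model.
* **Objective intelligibility** — the standard STOI measure
  (one-third-octave band envelope correlations over 384 ms segments),
  cross-checked against an independent implementation.
* **Stimuli** — a deterministic generator of Matrix-style five-word
  pseudo-sentences (harmonic carrier, gliding formants, syllabic 2–8 Hz
  envelopes) and the concatenate-five-times / extract-the-fourth
  presentation protocol that gives the batch filter > 4 s of
  initialisation.
* **A simulated listening study** — 15 psychometric listeners titrated to
  their individual RT60 at 50% word recognition, a six-condition
  crossover test with test/retest, paired preference ratings, and the
  statistical pipeline: rationalized arcsine (RAU) transform, REML mixed
  models with a subject random intercept and Šidák-corrected pairwise
  contrasts, Bonferroni-corrected one-sample t tests, and ICC(3,1)
  test-retest reliability.

## Worked example

```r
library(cidereverb)

# a virtual 7 x 6 x 3.5 m room tuned to RT60 = 1.0 s, head at 1.9 m
spec <- room_spec_for_rt60(1.0)
ir   <- simulate_rir(spec, ear = "left", seed = 1)
compute_drr(ir)        # -8.73 dB  (direct vs reverberant energy)
estimate_rt60(ir)      #  1.24 s   (Schroeder T30 of the specular shoebox)

# reverberate a synthetic sentence and dereverberate it
sent   <- generate_pseudo_sentence(101)
reverb <- apply_protocol(sent, ir, processor = "none")
wpe    <- apply_protocol(sent, ir, processor = "wpe")
wpepf  <- apply_protocol(sent, ir, processor = "wpepf")
compute_stoi(sent$samples, reverb$audio)$value   # 0.610
compute_stoi(sent$samples, wpe$audio)$value      # 0.628
compute_stoi(sent$samples, wpepf$audio)$value    # 0.641
```

The three STOI values tell the core story: reverberation at RT60 = 1 s
degrades the predicted intelligibility of the sentence, WPE recovers part
of it, and the post-filter adds a further margin. A full simulated study
wraps this chain in a listener panel:

```r
res <- simulate_study(n_listeners = 15, seed = 1)
res
#> Simulated study: 15 listeners, median RT60_50% = 1.00 s
#> Mean percent correct by condition:
#>        clean    clean_wpe  clean_wpepf       reverb   reverb_wpe reverb_wpepf
#>         97.3         97.5         97.6         55.8         65.8         68.2
```

Both algorithms significantly beat unprocessed reverberation in the
mixed-model contrasts, neither touches clean speech, and the preference
ratings favour the processed conditions — the qualitative pattern such a
listening study is designed to detect.

A thin command-line front end over the same functions ships in
`inst/cli/cidereverb.R` (subcommands `simulate-rir`, `dereverb`, `stoi`,
`make-stimuli`, `run-study`).

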