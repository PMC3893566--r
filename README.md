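# l1census

Analysis pipeline for a quantitative census of neocortical **layer 1 (L1)
interneurons** — the GABAergic cells that populate the most superficial
cortical lamina — from patch-clamp recordings, 3D reconstructions and paired
recordings. It is aimed at cellular electrophysiologists and neuroanatomists
who need reproducible, scriptable versions of the standard L1 analyses:

* **Firing-pattern (e-type) classification.** ISIs of a step-evoked train are
  regressed on AP order (`ISI_k = a + b·k + ε`); the decision tree uses the
  residual RMS (threshold 30 ms), the slope (threshold 1 ms/AP), silent
  periods (> 100 ms) and burst/doublet rules (25 ms) to assign
  cAC / cNAC / bNAC / cSTUT / cIR labels.
* **Morphometrics.** SWC in/out, slice-shrinkage correction, segment
  decomposition with centrifugal branch order, and a 44-feature battery
  (extents, moments, densities, tortuosity, branch angles, H/V ratios) per
  cell.
* **Cluster validation.** Feature power (between-class variance share), PCA,
  Fisher LDA, outlier flagging, and a 10x10-fold cross-validation with label
  randomization as the overfitting control.
* **Synaptic physiology.** IPSP amplitude (peak-to-peak), 20–80% rise/decay
  times, latency, CV; GABA_A / GABA_B / GABA_A+B receptor-type classification
  (single-AP response with rise < 60 ms vs train-only responses at >= 40 Hz);
  double-Gaussian rise-time mixture; amplitude rundown; gap-junction coupling
  coefficients (post/pre deflection ratio); pharmacological block accounting.
* **Circuit statistics.** Connection probabilities with exact binomial
  intervals, morpho-electrical cross-tabulations, putative-contact
  (apposition) detection, and Nernst reversal potentials.
* **Synthetic-data generators** for all of the above — spike trains per
  firing type, stochastic branching morphologies per morphological class,
  IPSP trains with a cooperative G-protein cascade for the slow component,
  and probed pair populations — every one seeded and with ground truth
  attached, so the whole pipeline is testable as parameter recovery.

## Worked example

```r
library(l1census)

# a stuttering cell: generate, detect spikes, classify
tr  <- generate_spike_response(etype_gen_defaults("cSTUT", seed = 1))
lab <- classify_etype(detect_spikes(tr))
print(lab)
#> <etype_label> cSTUT: slope 0.04, RMS 52.53, max gap 202 ms

# a mixed GABA_A+B connection probed with one AP and a 40 Hz train
sp    <- synapse_gen_spec("GABA_AB", rundown_rate = 0, seed = 2)
one   <- extract_ipsp(generate_paired_recording(sp, 100))
train <- extract_ipsp(generate_paired_recording(sp, 100 + 25 * (0:14)))
print(one)
#> <ipsp_features> amp 2.04 mV, rise 4.5 ms, decay 54.2 ms, latency 1.2 ms, CV 0.02
classify_receptor(one, train)
#> <receptor_class> GABA_AB (single-AP response: TRUE, rise 4.5 ms)

# reversal potentials from the recording solutions (mM, 34 C)
nernst(-1, c_in = 10,  c_out = 133.5)   # chloride  -> -68.6 mV
nernst(+1, c_in = 120, c_out = 2.5)     # potassium -> -102.5 mV
```

The stuttering cell is flagged by its poor ISI-regression fit (RMS 53 > 30)
plus a 202 ms silent period; the connection is mixed because a single AP
already evokes a fast (4 ms rise) IPSP while the train response carries an
excess slow charge component. A full synthetic census — all firing types,
all morphological classes, receptor classification and connection
probabilities — runs with `run_l1_demo(seed = 1)` and writes a JSON report.

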