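// Synthetic demonstration network (not derived from any published model):
// winter -> sprinkler, winter -> rain, sprinkler -> wet_grass,
// rain -> wet_grass, wet_grass -> slippery.
network garden_synthetic {
}
variable winter {
  type discrete [ 2 ] { no, yes };
}
variable sprinkler {
  type discrete [ 2 ] { off, on };
}
variable rain {
  type discrete [ 2 ] { no, yes };
}
variable wet_grass {
  type discrete [ 2 ] { dry, wet };
}
variable slippery {
  type discrete [ 2 ] { no, yes };
}
probability ( winter ) {
  table 0.4, 0.6;
}
probability ( sprinkler | winter ) {
  (no) 0.25, 0.75;
  (yes) 0.8, 0.2;
}
probability ( rain | winter ) {
  (no) 0.9, 0.1;
  (yes) 0.2, 0.8;
}
probability ( wet_grass | sprinkler, rain ) {
  (off, no) 0.95, 0.05;
  (on, no) 0.1, 0.9;
  (off, yes) 0.2, 0.8;
  (on, yes) 0.05, 0.95;
}
probability ( slippery | wet_grass ) {
  (dry) 0.9, 0.1;
  (wet) 0.25, 0.75;
}
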