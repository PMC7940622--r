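Shipped gait genomes (pattern-formation parameters, see ?read_genome):

genome_reference.txt  - optimized activation patterns for the unaltered
                        (digitigrade) foot; the endpoint of a staged,
                        warm-started GA run under the package's default
                        study conditions (CPG T = 0.747 s, posture gain 5,
                        reference pitch 0.3 rad, 15 s episodes, dt = 0.1 ms).
genome_heel36.txt     - activation patterns re-optimized after the heel
                        contact point was translated 36 mm inferiorly
                        (plantigrade morph), warm-started from the
                        reference genome.

Both files are plain text, one row per muscle: gamma, delta, mu1, mu2,
sigma1, sigma2. They are simulation artifacts of this package's optimizer
(synthetic, model-derived; not experimental data).
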