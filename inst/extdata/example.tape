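# Example run configuration: active convex CMCs on a small vesicle.
# Unspecified keys keep their defaults (f=1, w=1, kappa=20, rho=10%, c0=1).
nshell=10          # V = 5*nshell^2 + 2 = 502 vertices
kappa=28.5
w=2
c0=0.8
f=0.5
rho=0.10
mcsweeps=2000
iterations=20      # snapshots per run
seed=7
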