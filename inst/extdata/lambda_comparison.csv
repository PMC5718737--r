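source,method,medium,lambda,sigma,reference
IR06-P103d,MCNP5,water,0.692,0.021,present
IR06-P103d,MCNP5,perspex,0.691,0.021,present
IR06-P103d,TLD,perspex,0.689,0.058,present
IR06-P103d,consensus,perspex,0.690,NA,present
Theragenics 200,MCNP5,water,0.685,0.021,present
Theragenics 200,MC,water,0.686,0.03,published
Theragenics 200,TLD,solid water,0.650,0.08,published
MED3633,MC,water,0.677,0.02,published
MED3633,TLD,water,0.680,0.05,published
Best double-wall,TLD,solid water,0.69,0.08,published
Best double-wall,MC,water,0.67,0.02,published
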