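greek	latin
α	A
β	B
γ	G
δ	D
ε	E
ζ	Z
η	H
θ	T
ι	I
κ	K
λ	L
μ	M
ν	N
ξ	X
π	P
ρ	R
σ	S
ς	S
τ	T
υ	U
φ	F
χ	C
ψ	PS
ω	O
Α	A
Β	B
Γ	G
Δ	D
Ε	E
Ζ	Z
Η	H
Θ	T
Ι	I
Κ	K
Λ	L
Μ	M
Ν	N
Ξ	X
Π	P
Ρ	R
Σ	S
Τ	T
Υ	U
Φ	F
Χ	C
Ψ	PS
Ω	O
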