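# Scenario vocabulary for the synthetic teacher: shapes-and-colours
# child-directed speech.  Weights are Zipf-like token weights mimicking the
# observed frequency profile of one effective participant (top salient word
# ~50 tokens in ~600 words).  Variants are alternative phonemic renderings
# (pipe-separated); function and other (proper, non-salient) words carry
# variant pools, salient content words are rendered canonically.
# orth	phonemes	role	weight	variants
a	ah	function	53	ey|aa
red	r eh d	salient	51
thats	dh ae t s	function	33	dh ae|dh ah|dh eh|ae t s
green	g r iy n	salient	32
you	y uw	function	26	y ah|y uh
and	ae n d	function	24	ah n|eh n|n d
cross	k r ao s	salient	21
blue	b l uw	salient	21
heart	hh aa r t	salient	20
circle	s er k ah l	salient	17
we	w iy	function	15	w ah|w ih
that	dh ae t	other_word	14	dh ah t|dh eh|dh ah
the	dh ah	function	13	dh iy|dh eh
this	dh ih s	other_word	12	dh ih|dh ah s
is	ih z	function	12	ih s|ah z
look	l uh k	other_word	10	l ah k|uh k
can	k ae n	function	10	k ah n|k eh n
see	s iy	function	9	s ih|s ah
box	b aa k s	salient	9
star	s t aa r	salient	8
it	ih t	function	8	ah t|ih
what	w ah t	function	6	w aa t|w ah
sun	s ah n	salient	6
shape	sh ey p	salient	6
on	aa n	function	5	ah n|aa
ring	r ih ng	salient	5
big	b ih g	salient	5
square	s k w eh r	salient	5
white	w ay t	salient	4
moon	m uw n	salient	4
black	b l ae k	salient	4
small	s m ao l	salient	3
cube	k y uw b	salient	3
round	r aw n d	salient	3
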