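# Consonant clusters legal at syllable edges in English (approximation
# compiled from standard English phonotactics; editable).  Single consonants
# are always legal at either edge and are not listed.  Codas include
# syllabic-l sequences (d l, t l) heard in words like "model", "bottle".
[onset]
p l
p r
p y
b l
b r
b y
t r
t w
t y
d r
d w
d y
k l
k r
k w
k y
g l
g r
g w
f l
f r
f y
v y
th r
th w
sh r
hh y
m y
n y
s p
s t
s k
s f
s m
s n
s l
s w
s y
s p l
s p r
s p y
s t r
s t y
s k l
s k r
s k w
s k y
[coda]
p t
p s
p th
t s
t th
k t
k s
b z
d z
d l
t l
g z
ch t
jh d
f t
f s
f th
v d
v z
th s
dh d
dh z
s p
s t
s k
z d
sh t
zh d
m p
m z
m d
n t
n d
n ch
n jh
n th
n s
n z
ng k
ng z
l p
l b
l t
l d
l ch
l jh
l k
l f
l v
l th
l s
l z
l sh
l m
r p
r b
r t
r d
r ch
r jh
r k
r g
r f
r v
r th
r s
r z
r sh
r m
r n
r l
k s t
k s th
m p t
m p s
n t s
n d z
n th s
ng k s
ng k t
l t s
l d z
l f th
r t s
r d z
r l d
r l z
f t s
f th s
s t s
k t s
p t s
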