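%
1	posemo
2	negemo
3	anxiety
4	home
5	time
6	social
7	focuspast
8	pronoun
%
happy	1
happi*	1
hope*	1
joy*	1
relief	1
relax*	1
calm*	1
glad	1
good	1
great	1
love*	1
nice	1
better	1
enjoy*	1
positive	1
excit*	1
cheer*	1
sad	2
sadness	2
angry	2
anger	2
upset	2
hate*	2
awful	2
terrible	2
depress*	2
miser*	2
lonely	2
cry*	2
frustrat*	2
annoy*	2
disgust*	2
bad	2
worse	2
grief	2
hurt*	2
anxious	3
anxiety	3
worry	3
worri*	3
fear*	3
afraid	3
scare*	3
nervous	3
panic*	3
stress*	3
tense	3
dread*	3
uneasy	3
terrified	3
home	4
house*	4
flat	4
garden	4
kitchen	4
indoors	4
household	4
room	4
domestic	4
yesterday	5
today	5
tomorrow	5
now	5
soon	5
later	5
week*	5
month*	5
year*	5
day*	5
morning	5
evening	5
hour*	5
minute*	5
future	5
past	5
was	7
were	7
had	7
been	7
did	7
went	7
used	7
ago	7
before	7
previously	7
remember*	7
family	6
families	6
friend*	6
people	6
parent*	6
child*	6
neighbour*	6
colleague*	6
partner	6
social	6
together	6
community	6
everyone	6
visit*	6
i	8
me	8
my	8
mine	8
we	8
us	8
our	8
you	8
your	8
he	8
she	8
they	8
them	8
their	8
it	8
its	8
myself	8
ourselves	8
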