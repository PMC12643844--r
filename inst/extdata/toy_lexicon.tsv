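category	term
i	i
i	me
i	my
i	mine
i	myself
we	we
we	us
we	our
we	ours
we	ourselves
you	you
you	your
you	yours
you	yourself
you	yourselves
shehe	she
shehe	he
shehe	her
shehe	him
shehe	his
they	they
they	them
they	their
they	theirs
they	themselves
posemo	fulfilled
posemo	grateful
posemo	proud
posemo	whole
posemo	happy
posemo	joy
posemo	hope
negemo	empty
negemo	lost
negemo	pointless
negemo	hollow
negemo	miserable
negemo	gloomy
anx	anxiety
anx	anxious
anx	worry
anx	nervous
anx	fear
anx	panic
anger	angry
anger	rage
anger	furious
anger	annoyed
anger	hate
sad	sad
sad	tears
sad	grief
sad	sorrow
sad	crying
assent	yes
assent	agree
assent	ok
assent	okay
assent	indeed
assent	content
negate	no
negate	not
negate	never
negate	none
negate	cannot
compare	better
compare	worse
compare	more
compare	less
compare	than
compare	best
certain	certain
certain	always
certain	definitely
certain	sure
certain	settled
certain	steady
tentat	maybe
tentat	perhaps
tentat	possibly
tentat	seems
tentat	might
differ	but
differ	however
differ	although
differ	instead
differ	otherwise
interrog	when
interrog	what
interrog	why
interrog	how
interrog	which
interrog	wondering
interrog	questioning
cogproc	think
cogproc	know
cogproc	consider
cogproc	realize
cogproc	understand
insight	insight
insight	aware
insight	reflect
insight	clarity
insight	understanding
cause	because
cause	cause
cause	effect
cause	hence
cause	therefore
discrep	should
discrep	would
discrep	could
discrep	want
discrep	need
percept	sense
percept	notice
percept	observe
percept	perceive
percept	perception
see	see
see	look
see	view
see	watch
see	looking
feel	feel
feel	touch
feel	felt
feel	feeling
feel	warmth
hear	hear
hear	listen
hear	sound
hear	heard
hear	voice
bio	blood
bio	breath
bio	gene
bio	cell
bio	alive
body	body
body	head
body	hand
body	skin
body	heart
health	health
health	sick
health	pain
health	medicine
health	doctor
ingest	eat
ingest	food
ingest	drink
ingest	meal
ingest	dinner
sleep	sleep
sleep	insomnia
sleep	sleepless
sleep	dream
sleep	nightmare
sleep	awake
sleep	sleepy
social	social
social	talk
social	share
social	meet
social	together
family	family
family	mother
family	father
family	parent
family	sister
family	brother
friend	friend
friend	buddy
friend	pal
friend	companion
friend	mate
female	female
female	woman
female	girl
female	lady
female	mother
male	male
male	man
male	boy
male	gentleman
male	sir
drives	drive
drives	motivation
drives	goal
drives	ambition
drives	aspiration
drives	searching
affiliation	belong
affiliation	belonging
affiliation	ally
affiliation	member
affiliation	community
achieve	achieve
achieve	success
achieve	win
achieve	prize
achieve	accomplish
achieve	earn
power	power
power	control
power	dominate
power	strength
power	authority
reward	reward
reward	bonus
reward	gain
reward	benefit
reward	payoff
risk	risk
risk	danger
risk	unsafe
risk	threat
risk	gamble
work	work
work	job
work	office
work	task
work	career
money	money
money	cash
money	price
money	pay
money	wealth
relig	religion
relig	faith
relig	pray
relig	sacred
relig	spirit
death	death
death	die
death	dead
death	grave
death	mortal
relativ	relative
relativ	near
relativ	far
relativ	close
relativ	distance
motion	move
motion	go
motion	come
motion	walk
motion	run
space	space
space	place
space	area
space	room
space	location
time	time
time	hour
time	day
time	moment
time	year
focuspast	was
focuspast	were
focuspast	had
focuspast	yesterday
focuspast	ago
focuspresent	is
focuspresent	am
focuspresent	are
focuspresent	today
focuspresent	now
focusfuture	will
focusfuture	shall
focusfuture	future
focusfuture	tomorrow
focusfuture	soon
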